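#' Chebyshev type-II filter design in second-order sections
#'
#' Designs a digital Chebyshev type-II filter and returns it as cascaded
#' second-order sections (biquads). High-order IIR designs — the order-18
#' bandpass used for broadband EEG conditioning in particular — are
#' numerically unstable when collapsed to a single transfer-function
#' polynomial in double precision, so the design is kept in zero-pole-gain
#' form throughout (closed-form analog prototype, s-plane band transform,
#' bilinear transform) and only converted to order-2 polynomials at the
#' very end.
#'
#' @param order total filter order of the realized digital filter. For
#'   `type = "pass"` and `type = "stop"` this must be even; the underlying
#'   lowpass prototype has order `order / 2`.
#' @param band corner (stopband-edge) frequency in Hz: one value for
#'   `low`/`high`, a length-2 vector for `pass`/`stop`.
#' @param fs sampling frequency, Hz.
#' @param type filter type: `"pass"`, `"stop"`, `"low"` or `"high"`.
#' @param rs stopband attenuation in dB (design parameter of the
#'   Chebyshev type-II family; default 40).
#' @return an object of class `"sos_filter"`: a list with `sos` (matrix,
#'   one row per section, columns b0 b1 b2 a0 a1 a2), `gain` (scalar) and
#'   the design parameters.
#' @examples
#' flt <- design_cheby2(18, c(0.5, 90), fs = 250, type = "pass")
#' nrow(flt$sos)  # 9 biquads
#' @export
design_cheby2 <- function(order, band, fs, type = c("pass", "stop", "low", "high"),
                          rs = 40) {
  type <- match.arg(type)
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order))
    stop("'order' must be a positive integer")
  if (fs <= 0) stop("'fs' must be positive")
  two_sided <- type %in% c("pass", "stop")
  if (two_sided) {
    if (length(band) != 2L || diff(band) <= 0)
      stop("'band' must be an increasing frequency pair for pass/stop filters")
    if (order %% 2 != 0)
      stop("'order' must be even for pass/stop filters (it is the realized order)")
    n_proto <- order / 2L
  } else {
    if (length(band) != 1L) stop("'band' must be a single corner frequency")
    n_proto <- order
  }
  if (any(band <= 0) || any(band >= fs / 2))
    stop("'band' must lie strictly inside (0, fs/2)")

  zpg <- cheby2_zpk(n_proto, rs, band / (fs / 2), type)
  sos_from_zpk(zpg$zero, zpg$pole, zpg$gain,
               meta = list(order = order, band = band, fs = fs,
                           type = type, rs = rs))
}

# Digital Chebyshev type-II design kept in zero-pole-gain form.
# Analog prototype after Stearns & David; band transform and bilinear
# mapping delegated to the signal package's s-plane machinery.
cheby2_zpk <- function(n, rs, W, type) {
  stop_ <- type %in% c("stop", "high")
  T <- 2
  W <- 2 / T * tan(pi * W / T)          # prewarp
  lambda <- 10^(rs / 20)
  phi <- log(lambda + sqrt(lambda^2 - 1)) / n
  theta <- pi * ((1:n) - 0.5) / n
  alpha <- -sinh(phi) * sin(theta)
  beta <- cosh(phi) * cos(theta)
  if (n %% 2) {
    zero <- 1i / cos(theta[c(seq_len((n - 1) / 2), ((n + 3) / 2):n)])
  } else {
    zero <- 1i / cos(theta)
  }
  pole <- 1 / (alpha^2 + beta^2) * (alpha - 1i * beta)
  gain <- abs(Re(prod(pole) / prod(zero)))
  zpg <- signal::Zpg(zero = zero, pole = pole, gain = gain)
  zpg <- signal::sftrans(zpg, W = W, stop = stop_)
  signal::bilinear(zpg, T = T)
}

# Pair digital zeros/poles into second-order sections. Poles closest to
# the unit circle are paired first, each with the nearest available zero
# pair, which keeps per-section peaking small.
sos_from_zpk <- function(zero, pole, gain, meta = list()) {
  if (max(Mod(pole)) >= 1)
    stop("unstable design: a pole lies on or outside the unit circle")
  zg <- conj_group(zero)
  pg <- conj_group(pole)
  # order pole groups: nearest to unit circle first
  pg <- pg[order(vapply(pg, function(p) max(Mod(p)), 0), decreasing = TRUE)]
  sos <- matrix(0, nrow = 0, ncol = 6)
  for (pp in pg) {
    if (length(zg)) {
      d <- vapply(zg, function(zz) min(Mod(zz[1] - pp[1]), Mod(zz[1] - Conj(pp[1]))), 0)
      i <- which.min(d)
      zz <- zg[[i]]
      zg[[i]] <- NULL
    } else {
      zz <- complex(0)
    }
    b <- Re(poly_from_roots(zz))
    a <- Re(poly_from_roots(pp))
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos <- rbind(sos, c(b, a))
  }
  # any leftover zeros would mean an improper transfer function
  if (length(zg)) stop("internal error: more zeros than poles in SOS pairing")
  structure(c(list(sos = sos, gain = gain), meta), class = "sos_filter")
}

# group a conjugate-symmetric set of roots into conjugate pairs / reals;
# reals are themselves paired two at a time (one may remain single).
conj_group <- function(r, tol = 1e-8) {
  if (!length(r)) return(list())
  scale <- max(Mod(r), 1)
  is_real <- abs(Im(r)) < tol * scale
  reals <- Re(r[is_real])
  cplx <- r[!is_real]
  cplx <- cplx[Im(cplx) > 0]
  out <- lapply(cplx, function(z) c(z, Conj(z)))
  reals <- sort(reals)
  while (length(reals) >= 2) {
    out <- c(out, list(complex(real = reals[1:2])))
    reals <- reals[-(1:2)]
  }
  if (length(reals) == 1) out <- c(out, list(complex(real = reals)))
  out
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Apply a second-order-sections filter (single pass)
#'
#' @param flt an `"sos_filter"` from [design_cheby2()].
#' @param x numeric or complex vector.
#' @return filtered vector of the same length.
#' @export
sos_filter_apply <- function(flt, x) {
  stopifnot(inherits(flt, "sos_filter"))
  cplx <- is.complex(x)
  run <- function(v) {
    for (i in seq_len(nrow(flt$sos))) {
      b <- flt$sos[i, 1:3]
      a <- flt$sos[i, 4:6]
      v <- as.numeric(signal::filter(b, a, v))
    }
    v * flt$gain
  }
  if (cplx) complex(real = run(Re(x)), imaginary = run(Im(x))) else run(x)
}

#' Zero-phase (forward-backward) SOS filtering
#'
#' Applies the filter forward and backward so the net phase response is
#' zero and the amplitude response is squared. Edges are handled by
#' odd-reflection padding before filtering, which suppresses start-up
#' transients; `padlen` defaults to 250 samples (1 s at the pipeline's
#' 250 Hz working rate, on the order of the settling time of the
#' narrowest filters used here) or the signal length minus one, whichever
#' is smaller.
#'
#' @inheritParams sos_filter_apply
#' @param padlen padding length in samples at each edge.
#' @return filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(flt, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 250L)
  if (padlen < 0 || padlen >= n) stop("'padlen' must be in [0, length(x))")
  pad <- function(v) {
    if (padlen == 0) return(v)
    pre <- 2 * v[1] - v[seq(padlen + 1, 2)]
    post <- 2 * v[n] - v[seq(n - 1, n - padlen)]
    c(pre, v, post)
  }
  y <- pad(x)
  y <- sos_filter_apply(flt, y)
  y <- rev(sos_filter_apply(flt, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

# complex rev keeps class; rev() works elementwise for complex too

#' Frequency response of an SOS filter
#'
#' @inheritParams sos_filter_apply
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate; defaults to the design rate stored in `flt`.
#' @return complex response at `f`.
#' @export
sos_freq_response <- function(flt, f, fs = flt$fs) {
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  h <- rep(flt$gain + 0i, length(z))
  for (i in seq_len(nrow(flt$sos))) {
    b <- flt$sos[i, 1:3]
    a <- flt$sos[i, 4:6]
    h <- h * (b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2)
  }
  h
}

#' Gaussian narrowband filter (spectral domain)
#'
#' Multiplies the FFT of a real signal by a Gaussian centred at `fc`
#' whose full width at half maximum (on the amplitude spectrum) is
#' `fwhm`: unit gain at `fc`, gain 0.5 at `fc +/- fwhm/2`. This is the
#' narrowband step used to build the RESS covariance matrices.
#'
#' @param x real signal vector.
#' @param fs sampling rate, Hz.
#' @param fc centre frequency, Hz (0 < fc < fs/2).
#' @param fwhm full width at half maximum, Hz.
#' @return filtered real vector.
#' @export
gaussian_narrowband <- function(x, fs, fc, fwhm) {
  if (fc <= 0 || fc >= fs / 2) stop("'fc' must lie in (0, fs/2)")
  if (fwhm <= 0) stop("'fwhm' must be positive")
  if (fwhm >= fc) stop("'fwhm' must be smaller than 'fc'")
  n <- length(x)
  f <- fft_freqs(n, fs)
  g <- exp(-4 * log(2) * (abs(f) - fc)^2 / fwhm^2)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# two-sided FFT bin frequencies (negative for the upper half)
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}
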