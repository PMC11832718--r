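#' Complex-demodulation settings
#'
#' Filter parameters of the complex demodulation stage: a narrow
#' zero-phase Chebyshev type-II bandpass isolating the 40 Hz component
#' (corner frequencies 39.5 and 40.5 Hz), followed by frequency shifting
#' to baseband and a zero-phase Chebyshev type-II lowpass (2 Hz) that
#' removes the double-frequency image. Orders are the realized filter
#' orders; corners are the type-II stopband edges.
#'
#' @param f demodulation frequency, Hz (default 40).
#' @param bp_band bandpass corner pair, Hz (default `c(39.5, 40.5)`).
#' @param lp_cutoff lowpass corner, Hz (default 2).
#' @param bp_order,lp_order realized filter orders (defaults 12 and 6).
#'   The bandpass order controls how much of the 1 Hz design band is
#'   usable passband: at order 8 the realized passband is only about
#'   +/- 0.2 Hz, which smears the envelope over roughly 2 s and lets
#'   onset energy bleed backwards into the pre-stimulus baseline; order
#'   12 keeps the transition inside the design band while remaining
#'   stable in second-order sections.
#' @param rs stopband attenuation, dB.
#' @return list of class `"demod_settings"`.
#' @export
demod_settings <- function(f = 40, bp_band = c(39.5, 40.5), lp_cutoff = 2,
                           bp_order = 12L, lp_order = 6L, rs = 40) {
  if (!(bp_band[1] < f && f < bp_band[2]))
    stop("'bp_band' must bracket the demodulation frequency")
  if (lp_cutoff <= 0 || lp_cutoff >= diff(bp_band) * 4)
    stop("'lp_cutoff' must be positive and small relative to the band")
  structure(list(f = f, bp_band = bp_band, lp_cutoff = lp_cutoff,
                 bp_order = as.integer(bp_order),
                 lp_order = as.integer(lp_order), rs = rs),
            class = "demod_settings")
}

#' Complex demodulation of a single-channel component
#'
#' Per trial: zero-phase narrowband bandpass around the stimulation
#' frequency, multiplication by `exp(-1i * 2 * pi * f * t)` (with `t`
#' the epoch's time axis relative to onset, so phases are comparable
#' across trials), then a zero-phase lowpass removing the component at
#' twice the carrier. For an input `a * cos(2 * pi * f * t + phi)` the
#' steady-state output satisfies `2 * Mod(z) ~ a` and `Arg(z) ~ phi`.
#'
#' Because the bandpass is only 1 Hz wide, its ringing (Gibbs) response
#' to any discontinuity persists for seconds. Generic odd-reflection
#' padding creates exactly such a discontinuity at the epoch edges (the
#' reflected carrier is phase-conjugated), so each epoch is instead
#' extended with a carrier-coherent continuation: a constant-envelope
#' 40 Hz tone whose amplitude and phase are estimated over the last
#' 0.5 s of each edge, held for 1 s and then tapered to zero with a
#' raised cosine over the remainder of the 5 s pad (long enough that
#' the taper's spectral footprint stays inside the passband). The
#' padding is trimmed after filtering.
#'
#' @param component a single-channel `"assr_epochs"` (e.g. the RESS
#'   component).
#' @param settings a [demod_settings()].
#' @return object of class `"assr_demod"`: list with complex matrix `z`
#'   (trials x samples), time axis `t`, `fs` and the settings.
#' @export
complex_demodulate <- function(component, settings = demod_settings()) {
  stopifnot(inherits(component, "assr_epochs"))
  if (n_channels(component) != 1)
    stop("complex demodulation expects a single-channel component")
  fs <- component$fs
  if (fs <= 2 * settings$bp_band[2])
    stop("bandpass band violates the Nyquist limit")
  bp <- design_cheby2(settings$bp_order, settings$bp_band, fs = fs,
                      type = "pass", rs = settings$rs)
  lp <- design_cheby2(settings$lp_order, settings$lp_cutoff, fs = fs,
                      type = "low", rs = settings$rs)
  t <- component$t
  P <- round(5 * fs)                         # pad samples per edge
  tp <- c(t[1] - rev(seq_len(P)) / fs, t, t[length(t)] + seq_len(P) / fs)
  osc <- exp(-1i * 2 * pi * settings$f * tp)
  keep <- P + seq_along(t)
  K <- n_epochs(component)
  z <- matrix(0i, nrow = K, ncol = length(t))
  for (k in seq_len(K)) {
    xp <- pad_carrier_coherent(component$data[k, 1, ], fs, settings$f, P, t)
    xbp <- sos_filtfilt(bp, xp)
    z[k, ] <- sos_filtfilt(lp, xbp * osc)[keep]
  }
  structure(list(z = z, t = t, fs = fs, settings = settings,
                 baseline_window = component$baseline_window),
            class = "assr_demod")
}

# extend a narrowband epoch with tapered constant-envelope carrier
# continuations matched in amplitude and phase at each edge; the taper
# must be several seconds long so its spectral footprint stays inside
# the 1 Hz passband and does not itself excite filter ringing
pad_carrier_coherent <- function(x, fs, f, P, t) {
  n <- length(x)
  W <- min(n, round(0.5 * fs))
  fit_edge <- function(idx) {
    tt <- t[idx]
    a <- 2 * mean(x[idx] * cos(2 * pi * f * tt))
    b <- -2 * mean(x[idx] * sin(2 * pi * f * tt))
    c(amp = sqrt(a^2 + b^2), phase = atan2(b, a))
  }
  flat <- min(P, round(1 * fs))
  taper <- c(rep(1, flat),
             0.5 * (1 + cos(pi * seq_len(P - flat) / max(P - flat, 1))))
  left <- fit_edge(seq_len(W))
  tl <- t[1] - rev(seq_len(P)) / fs
  padl <- rev(taper) * left["amp"] * cos(2 * pi * f * tl + left["phase"])
  right <- fit_edge(n - W + seq_len(W))
  tr <- t[n] + seq_len(P) / fs
  padr <- taper * right["amp"] * cos(2 * pi * f * tr + right["phase"])
  c(padl, x, padr)
}

#' Amplitude-modulation profile
#'
#' Trial mean of twice the demodulated modulus, minus the scalar mean of
#' that series over the baseline window:
#' `AM(t) = mean_k 2 |z(t, k)| - baseline_AM`.
#'
#' @param demod an `"assr_demod"`.
#' @param baseline_window baseline interval in seconds (defaults to the
#'   epoching baseline carried by the demod object).
#' @return object of class `"assr_modprofile"` with fields `t`, `am`,
#'   `am_baseline`, `K`.
#' @export
amplitude_modulation <- function(demod, baseline_window = NULL) {
  stopifnot(inherits(demod, "assr_demod"))
  if (is.null(baseline_window)) baseline_window <- demod$baseline_window
  bl <- demod$t >= baseline_window[1] & demod$t < baseline_window[2]
  if (!any(bl)) stop("baseline window contains no samples")
  am_raw <- colMeans(2 * Mod(demod$z))
  base <- mean(am_raw[bl])
  structure(list(t = demod$t, am = am_raw - base, am_baseline = base,
                 K = nrow(demod$z), baseline_window = baseline_window),
            class = "assr_modprofile")
}

#' Inter-trial phase coherence profile
#'
#' Resultant length of the across-trial unit phasors at each time point,
#' minus its baseline-window mean:
#' `ITPC(t) = | mean_k z(t, k) / |z(t, k)| | - baseline_ITPC`.
#' The pre-baseline series lies in `[0, 1]`: 1 means perfectly
#' consistent phase across trials, 0 uniform dispersion. Samples where
#' the modulus vanishes (below `1e-12` of the series maximum) are
#' excluded from the phasor average; a time point with no valid trial is
#' carried as `NA` and excluded from any subsequent fit.
#'
#' @inheritParams amplitude_modulation
#' @return object of class `"assr_modprofile"` with fields `t`, `itpc`,
#'   `itpc_baseline`, `K`.
#' @export
itpc <- function(demod, baseline_window = NULL) {
  stopifnot(inherits(demod, "assr_demod"))
  if (nrow(demod$z) < 2) stop("ITPC needs at least 2 trials")
  if (is.null(baseline_window)) baseline_window <- demod$baseline_window
  bl <- demod$t >= baseline_window[1] & demod$t < baseline_window[2]
  if (!any(bl)) stop("baseline window contains no samples")
  m <- Mod(demod$z)
  thresh <- 1e-12 * max(m)
  ph <- demod$z / m
  ph[m < thresh] <- NA_complex_
  itpc_raw <- apply(ph, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    Mod(mean(col))
  })
  base <- mean(itpc_raw[bl], na.rm = TRUE)
  structure(list(t = demod$t, itpc = itpc_raw - base, itpc_baseline = base,
                 K = nrow(demod$z), baseline_window = baseline_window),
            class = "assr_modprofile")
}

#' Combined AM + ITPC profile
#'
#' @inheritParams amplitude_modulation
#' @return an `"assr_modprofile"` carrying both series and both
#'   baselines.
#' @export
modulation_profile <- function(demod, baseline_window = NULL) {
  am <- amplitude_modulation(demod, baseline_window)
  pc <- itpc(demod, baseline_window)
  structure(list(t = am$t, am = am$am, am_baseline = am$am_baseline,
                 itpc = pc$itpc, itpc_baseline = pc$itpc_baseline,
                 K = am$K, baseline_window = am$baseline_window),
            class = "assr_modprofile")
}

#' @export
print.assr_modprofile <- function(x, ...) {
  cat(sprintf("<assr_modprofile> K=%d trials, %d samples [%g, %g] s%s%s\n",
              x$K, length(x$t), min(x$t), max(x$t),
              if (!is.null(x$am)) " +am" else "",
              if (!is.null(x$itpc)) " +itpc" else ""))
  invisible(x)
}

#' Average ASSR band power
#'
#' Per-epoch power in a narrow band around the stimulation frequency
#' over the stimulation window, averaged across epochs. The estimate is
#' a rectangular-window periodogram summed over the band's FFT bins,
#' scaled so a sine of amplitude `a` at `f0` yields `a^2 / 2`.
#'
#' @param component a single-channel `"assr_epochs"`.
#' @param f0 centre frequency, Hz (default 40).
#' @param halfwidth half band width, Hz (default 0.5).
#' @param window analysis window in seconds, default `c(0, 6)`.
#' @return scalar band power (squared signal units).
#' @export
assr_bandpower <- function(component, f0 = 40, halfwidth = 0.5,
                           window = c(0, 6)) {
  stopifnot(inherits(component, "assr_epochs"))
  if (n_channels(component) != 1)
    stop("assr_bandpower expects a single channel; see topography_40hz")
  sel <- component$t >= window[1] & component$t < window[2]
  if (sum(sel) / component$fs < 2)
    stop("band power needs a window of at least 2 s (0.5 Hz resolution)")
  mean(vapply(seq_len(n_epochs(component)), function(k)
    band_power_series(component$data[k, 1, sel], component$fs, f0, halfwidth),
    0))
}

# one-sided band power of a single series via periodogram bins
band_power_series <- function(x, fs, f0, halfwidth) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  X <- fft(x)
  bins <- which(f >= f0 - halfwidth & f <= f0 + halfwidth & f > 0)
  sum(2 * Mod(X[bins])^2 / n^2)
}

#' 40 Hz band-power topography
#'
#' Evaluates [assr_bandpower()] for every channel of an all-channel
#' epoch container.
#'
#' @param epochs an `"assr_epochs"` object.
#' @inheritParams assr_bandpower
#' @return object of class `"assr_topography"`: list with
#'   `channel_labels`, `value` (named per-channel band power) and an
#'   optional `p` slot filled by [permutation_topography()].
#' @export
topography_40hz <- function(epochs, f0 = 40, halfwidth = 0.5,
                            window = c(0, 6)) {
  stopifnot(inherits(epochs, "assr_epochs"))
  sel <- epochs$t >= window[1] & epochs$t < window[2]
  if (sum(sel) / epochs$fs < 2)
    stop("band power needs a window of at least 2 s")
  vals <- vapply(seq_len(n_channels(epochs)), function(ch)
    mean(vapply(seq_len(n_epochs(epochs)), function(k)
      band_power_series(epochs$data[k, ch, sel], epochs$fs, f0, halfwidth),
      0)), 0)
  structure(list(channel_labels = epochs$channel_labels,
                 value = setNames(vals, epochs$channel_labels), p = NULL),
            class = "assr_topography")
}

#' @export
print.assr_topography <- function(x, ...) {
  cat(sprintf("<assr_topography> %d channels, max %s = %.3g\n",
              length(x$value), names(which.max(x$value)), max(x$value)))
  invisible(x)
}

#' Short-time Fourier transform of a component
#'
#' Hann-windowed STFT per trial, used as the time-frequency input of
#' [ersp()]. Defaults: 0.5 s window, 90 percent overlap.
#'
#' @param component a single-channel `"assr_epochs"`.
#' @param win_s window length, seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list with complex array `X` (trials x freq x time),
#'   frequency axis `f` (Hz) and time axis `t` (s, window centres).
#' @export
stft_component <- function(component, win_s = 0.5, overlap = 0.9) {
  stopifnot(inherits(component, "assr_epochs"))
  if (n_channels(component) != 1) stop("stft_component expects one channel")
  fs <- component$fs
  nwin <- round(win_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n <- length(component$t)
  starts <- seq(1L, n - nwin + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  nf <- floor(nwin / 2) + 1L
  K <- n_epochs(component)
  X <- array(0i, dim = c(K, nf, length(starts)))
  for (k in seq_len(K)) {
    x <- component$data[k, 1, ]
    for (j in seq_along(starts)) {
      seg <- x[starts[j]:(starts[j] + nwin - 1L)] * h
      X[k, , j] <- fft(seg)[seq_len(nf)]
    }
  }
  list(X = X, f = (seq_len(nf) - 1) * fs / nwin,
       t = component$t[starts] + (nwin - 1) / (2 * fs))
}

#' Evoked spectral perturbation (ERSP)
#'
#' Trial-mean squared modulus of a time-frequency stack:
#' `ERSP(f, t) = mean_n |X(f, t, n)|^2`. Non-negative everywhere and
#' invariant to trial sign flips.
#'
#' @param tf complex array, trials x freq x time (e.g.
#'   `stft_component()$X`).
#' @return real matrix, freq x time.
#' @export
ersp <- function(tf) {
  if (is.list(tf)) tf <- tf$X
  d <- dim(tf)
  if (is.null(d) || length(d) != 3 || d[1] < 1)
    stop("'tf' must be a non-empty trials x freq x time array")
  apply(Mod(tf)^2, c(2, 3), mean)
}

#' Resize a real map by bilinear interpolation
#'
#' Utility for exporting ERSP maps on a fixed grid (e.g. 224 x 224 for
#' image classifiers).
#'
#' @param map real matrix.
#' @param nrow_out,ncol_out target dimensions.
#' @return resized matrix.
#' @export
resize_map <- function(map, nrow_out = 224L, ncol_out = 224L) {
  ri <- seq(1, nrow(map), length.out = nrow_out)
  ci <- seq(1, ncol(map), length.out = ncol_out)
  r0 <- floor(ri); r1 <- pmin(r0 + 1, nrow(map)); fr <- ri - r0
  c0 <- floor(ci); c1 <- pmin(c0 + 1, ncol(map)); fc <- ci - c0
  out <- matrix(0, nrow_out, ncol_out)
  for (j in seq_len(ncol_out)) {
    colA <- map[, c0[j]] * (1 - fc[j]) + map[, c1[j]] * fc[j]
    out[, j] <- colA[r0] * (1 - fr) + colA[r1] * fr
  }
  out
}
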