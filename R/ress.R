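#' RESS settings
#'
#' Parameters of the rhythmic entrainment source separation filter: the
#' target frequency and the Gaussian narrowband widths used to build the
#' signal covariance `S` (at `f0`, FWHM `fwhm_signal`) and the reference
#' covariance `R` (average of the two neighbours at
#' `f0 +/- neighbor_dist`, FWHM `fwhm_neighbor`), computed over the
#' stimulation window.
#'
#' @param f0 target frequency, Hz (default 40).
#' @param fwhm_signal FWHM of the signal filter, Hz (default 0.5).
#' @param neighbor_dist distance of the neighbour frequencies, Hz
#'   (default 1).
#' @param fwhm_neighbor FWHM of the neighbour filters, Hz (default 1).
#' @param window covariance window in seconds relative to onset,
#'   default `c(0, 6)` (the full stimulation).
#' @return list of class `"ress_settings"`.
#' @export
ress_settings <- function(f0 = 40, fwhm_signal = 0.5, neighbor_dist = 1,
                          fwhm_neighbor = 1, window = c(0, 6)) {
  if (f0 <= 0) stop("'f0' must be positive")
  if (fwhm_signal <= 0 || fwhm_neighbor <= 0) stop("FWHMs must be positive")
  if (neighbor_dist <= fwhm_signal / 2)
    stop("'neighbor_dist' must exceed half the signal FWHM")
  structure(list(f0 = f0, fwhm_signal = fwhm_signal,
                 neighbor_dist = neighbor_dist,
                 fwhm_neighbor = fwhm_neighbor, window = window),
            class = "ress_settings")
}

#' Narrowband covariance matrices for RESS
#'
#' Filters every channel of every epoch with a spectral Gaussian (over
#' the full epoch, for frequency resolution), restricts to the
#' stimulation window, and averages the per-trial channel covariance
#' matrices: `S` at the target frequency, `R` as the mean of the two
#' neighbour-frequency covariances. Each covariance is normalized by its
#' filter's equivalent noise bandwidth so that `S` and `R` are power
#' densities on a common scale: spectrally flat noise then gives
#' `S = R` in expectation even though the signal and neighbour filters
#' have different widths. The normalization is a scalar per matrix, so
#' eigenvectors are unaffected; eigenvalues become per-Hz power ratios.
#'
#' @param epochs an `"assr_epochs"` object (>= 2 channels).
#' @param settings a [ress_settings()].
#' @return list with symmetric matrices `S` and `R`.
#' @export
narrowband_covariances <- function(epochs, settings = ress_settings()) {
  stopifnot(inherits(epochs, "assr_epochs"))
  if (n_channels(epochs) < 2) stop("RESS needs at least 2 channels")
  w <- settings$window
  sel <- epochs$t >= w[1] & epochs$t < w[2]
  if (!any(sel)) stop("covariance window contains no samples")
  if (sum(sel) < n_channels(epochs))
    warning("fewer samples than channels in the covariance window; ",
            "the covariance is rank deficient and shrinkage is required")
  cov_at <- function(fc, fwhm) {
    acc <- matrix(0, n_channels(epochs), n_channels(epochs))
    for (k in seq_len(n_epochs(epochs))) {
      filt <- t(apply(epochs$data[k, , , drop = TRUE], 1, gaussian_narrowband,
                      fs = epochs$fs, fc = fc, fwhm = fwhm))
      if (n_channels(epochs) == 1) filt <- matrix(filt, nrow = 1)
      xw <- filt[, sel, drop = FALSE]
      xw <- xw - rowMeans(xw)
      acc <- acc + tcrossprod(xw) / (ncol(xw) - 1)
    }
    # equivalent noise bandwidth of the Gaussian gain, integral of g^2, Hz
    enbw <- fwhm * sqrt(pi / (8 * log(2)))
    acc / n_epochs(epochs) / enbw
  }
  S <- cov_at(settings$f0, settings$fwhm_signal)
  R <- (cov_at(settings$f0 - settings$neighbor_dist, settings$fwhm_neighbor) +
        cov_at(settings$f0 + settings$neighbor_dist, settings$fwhm_neighbor)) / 2
  list(S = (S + t(S)) / 2, R = (R + t(R)) / 2)
}

#' Generalized eigendecomposition for RESS
#'
#' Solves the symmetric-definite generalized eigenproblem `S v = lambda
#' R v` with the reference covariance shrunk towards a scaled identity,
#' `R_reg = (1 - gamma) R + gamma mean(diag(R)) I`, which guards against
#' the rank deficiency of covariances built from 0.5 Hz-wide filtered
#' data. Solved via the Cholesky factor of `R_reg` (never by explicit
#' inversion); eigenpairs are returned in descending eigenvalue order,
#' eigenvectors normalized to unit norm with the sign fixed so each
#' vector's largest-magnitude element is positive. The eigenvectors of a
#' generalized problem are not mutually orthogonal.
#'
#' @param S,R symmetric matrices of equal size.
#' @param shrinkage shrinkage fraction gamma in `[0, 1]` (default 0.01).
#' @return list with `values` (descending) and `vectors` (columns).
#' @export
ress_decompose <- function(S, R, shrinkage = 0.01) {
  if (!isTRUE(all.equal(S, t(S))) || !isTRUE(all.equal(R, t(R))))
    stop("'S' and 'R' must be symmetric")
  if (!all(dim(S) == dim(R))) stop("'S' and 'R' must have the same size")
  if (shrinkage < 0 || shrinkage > 1) stop("'shrinkage' must be in [0, 1]")
  n <- nrow(R)
  Rreg <- (1 - shrinkage) * R + shrinkage * mean(diag(R)) * diag(n)
  U <- tryCatch(chol(Rreg), error = function(e)
    stop("reference covariance is not positive definite after shrinkage ",
         sprintf("(gamma = %g): %s", shrinkage, conditionMessage(e))))
  Ui <- backsolve(U, diag(n))
  M <- t(Ui) %*% S %*% Ui
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vecs <- Ui %*% e$vectors
  vecs <- apply(vecs, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  list(values = e$values, vectors = matrix(vecs, nrow = n))
}

#' Project epochs through a spatial filter
#'
#' Applies the RESS weights to every trial:
#' `component(t) = sum_i w_i x_i(t)`, returning a single-channel epoch
#' container.
#'
#' @param epochs an `"assr_epochs"` object.
#' @param weights numeric vector, one weight per channel.
#' @return an `"assr_epochs"` with one channel labelled `"RESS"`.
#' @export
project_component <- function(epochs, weights) {
  stopifnot(inherits(epochs, "assr_epochs"))
  if (length(weights) != n_channels(epochs))
    stop("weight length must equal the channel count")
  comp <- array(0, dim = c(n_epochs(epochs), 1, length(epochs$t)))
  for (k in seq_len(n_epochs(epochs)))
    comp[k, 1, ] <- drop(weights %*% epochs$data[k, , , drop = TRUE])
  out <- epochs
  out$data <- comp
  out$channel_labels <- "RESS"
  out
}

#' SNR spectrum of a component at the target frequency
#'
#' Power at the FFT bin nearest `f0` divided by the mean power of the
#' flanking bins (within `flank` Hz of `f0` but outside the `exclude`
#' neighbourhood), computed on the trial-averaged power spectrum over
#' the stimulation window. When the flank power underflows (noiseless
#' input), the returned value carries the attribute `capped = TRUE`.
#'
#' @param component a single-channel `"assr_epochs"`.
#' @param f0 target frequency, Hz.
#' @param exclude half-width of the excluded neighbourhood, Hz.
#' @param flank half-width of the flanking band, Hz.
#' @param window spectrum window in seconds, default `c(0, 6)`.
#' @return SNR as a power ratio (attribute `capped` flags a noiseless
#'   ceiling).
#' @export
snr_spectrum <- function(component, f0 = 40, exclude = 0.5, flank = 2,
                         window = c(0, 6)) {
  stopifnot(inherits(component, "assr_epochs"))
  sel <- component$t >= window[1] & component$t < window[2]
  if (sum(sel) / component$fs < 2)
    stop("SNR window must be at least 2 s for 0.5 Hz resolution")
  nw <- sum(sel)
  f <- fft_freqs(nw, component$fs)
  pw <- rep(0, nw)
  for (k in seq_len(n_epochs(component))) {
    X <- fft(component$data[k, 1, sel])
    pw <- pw + Mod(X)^2
  }
  pw <- pw / n_epochs(component)
  i0 <- which.min(abs(f - f0))
  fl <- which(abs(f - f0) > exclude & abs(f - f0) <= flank & f > 0)
  if (!length(fl)) stop("no flanking bins available")
  denom <- mean(pw[fl])
  if (denom <= pw[i0] * 1e-12) {
    out <- pw[i0] / max(denom, .Machine$double.xmin)
    attr(out, "capped") <- TRUE
    return(out)
  }
  out <- pw[i0] / denom
  attr(out, "capped") <- FALSE
  out
}

#' Run the full RESS stage
#'
#' Convenience wrapper: narrowband covariances, generalized
#' eigendecomposition, projection through the leading spatial filter,
#' and component SNR.
#'
#' @inheritParams narrowband_covariances
#' @param shrinkage shrinkage fraction for [ress_decompose()].
#' @return an object of class `"ress_result"`: list with `S`, `R`,
#'   `eigenvalues`, `weights`, `component` (single-channel epochs) and
#'   `snr`.
#' @export
ress <- function(epochs, settings = ress_settings(), shrinkage = 0.01) {
  covs <- narrowband_covariances(epochs, settings)
  dec <- ress_decompose(covs$S, covs$R, shrinkage)
  w <- dec$vectors[, 1]
  comp <- project_component(epochs, w)
  structure(list(S = covs$S, R = covs$R, eigenvalues = dec$values,
                 weights = setNames(w, epochs$channel_labels),
                 component = comp,
                 snr = snr_spectrum(comp, settings$f0,
                                    window = settings$window),
                 settings = settings),
            class = "ress_result")
}

#' @export
print.ress_result <- function(x, ...) {
  cat(sprintf("<ress_result> %d channels, top eigenvalue %.3g, SNR %.3g%s\n",
              length(x$weights), x$eigenvalues[1], as.numeric(x$snr),
              if (isTRUE(attr(x$snr, "capped"))) " (capped)" else ""))
  invisible(x)
}
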