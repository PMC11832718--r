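#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the channel mean is zero everywhere. Idempotent and invariant to a
#' common offset.
#'
#' @param raw an `"assr_raw"` recording.
#' @return the re-referenced recording.
#' @export
rereference_common_average <- function(raw) {
  stopifnot(inherits(raw, "assr_raw"))
  if (nrow(raw$data) < 2)
    stop("common-average reference needs at least 2 channels")
  raw$data <- sweep(raw$data, 2, colMeans(raw$data))
  raw
}

#' Resample a recording
#'
#' Anti-alias lowpass filtering (zero-phase Chebyshev type-II with
#' stopband edge at the target Nyquist frequency) followed by decimation
#' for integer rate ratios, or linear interpolation onto the new sample
#' grid otherwise. Event onsets are stored in seconds and are unchanged.
#'
#' @param raw an `"assr_raw"` recording.
#' @param target_fs target sampling rate, Hz (default 250).
#' @return resampled recording.
#' @export
resample_recording <- function(raw, target_fs = 250) {
  stopifnot(inherits(raw, "assr_raw"))
  if (target_fs > raw$fs) stop("'target_fs' must not exceed the current rate")
  if (target_fs < 2 * 90)
    warning("target rate below 180 Hz: the 0.5-90 Hz analysis band would alias")
  if (target_fs == raw$fs) return(raw)
  flt <- design_cheby2(10, 0.98 * target_fs / 2, fs = raw$fs,
                       type = "low", rs = 60)
  n_in <- ncol(raw$data)
  ratio <- raw$fs / target_fs
  n_out <- floor(n_in / ratio)
  filt <- t(apply(raw$data, 1, function(x) sos_filtfilt(flt, x)))
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, by = round(ratio), length.out = n_out)
    out <- filt[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(n_in) - 1) / raw$fs
    t_new <- (seq_len(n_out) - 1) / target_fs
    out <- t(apply(filt, 1, function(x) approx(t_old, x, xout = t_new)$y))
  }
  raw$data <- out
  raw$fs <- target_fs
  raw
}

#' Zero-phase Chebyshev type-II filtering of a recording
#'
#' Bandpass or bandstop filtering applied forward-backward per channel
#' (zero net phase, squared amplitude response), realized in
#' second-order sections. Defaults follow the pipeline's conditioning
#' stage: an order-18 bandpass for the 0.5-90 Hz analysis band and an
#' order-8 notch for 50 Hz line interference.
#'
#' @param raw an `"assr_raw"` recording.
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param band frequency pair in Hz.
#' @param order realized filter order (even).
#' @param rs stopband attenuation, dB.
#' @return the filtered recording.
#' @seealso [design_cheby2()], [sos_filtfilt()]
#' @export
cheby2_filter <- function(raw, kind = c("bandpass", "bandstop"),
                          band = if (match.arg(kind) == "bandpass") c(0.5, 90)
                                 else c(48, 52),
                          order = if (match.arg(kind) == "bandpass") 18L else 8L,
                          rs = 40) {
  stopifnot(inherits(raw, "assr_raw"))
  kind <- match.arg(kind)
  type <- if (kind == "bandpass") "pass" else "stop"
  flt <- design_cheby2(order, band, fs = raw$fs, type = type, rs = rs)
  raw$data <- t(apply(raw$data, 1, function(x) sos_filtfilt(flt, x)))
  raw
}

#' Artifact-cleaning hook
#'
#' Placeholder for component-based artifact removal (e.g. ICA with an
#' external classifier), which requires a trained model outside this
#' package's scope. Accepts a user-supplied cleaning function operating
#' on the raw container; by default the data pass through unchanged.
#'
#' @param raw an `"assr_raw"` recording.
#' @param cleaner optional function `raw -> raw`.
#' @return the (possibly cleaned) recording.
#' @export
artifact_clean_hook <- function(raw, cleaner = NULL) {
  stopifnot(inherits(raw, "assr_raw"))
  if (is.null(cleaner)) return(raw)
  out <- cleaner(raw)
  if (!inherits(out, "assr_raw")) stop("'cleaner' must return an assr_raw")
  out
}

#' Epoch a recording around stimulus onsets and baseline-correct
#'
#' Cuts one epoch per event over a half-open window `[start, stop)`
#' relative to onset, then subtracts, per epoch and channel, the scalar
#' mean over the baseline window. The onset sample index is
#' `round(t0 * fs)`; epoch length is identical across events. Events
#' whose window does not fit inside the recording are dropped with a
#' warning (count kept in the result).
#'
#' @param raw an `"assr_raw"` recording with events.
#' @param window epoch window in seconds relative to onset, default
#'   `c(-1, 6)`.
#' @param baseline_window baseline interval in seconds, default
#'   `c(-0.5, -0.25)`.
#' @return an `"assr_epochs"` object, epochs ordered by onset.
#' @export
epoch_and_baseline <- function(raw, window = c(-1, 6),
                               baseline_window = c(-0.5, -0.25)) {
  stopifnot(inherits(raw, "assr_raw"))
  if (!nrow(raw$events)) stop("no events to epoch around")
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
    stop("baseline window must lie inside the epoch window")
  fs <- raw$fs
  n <- ncol(raw$data)
  n_ep <- round((window[2] - window[1]) * fs)       # half-open [start, stop)
  rel <- seq_len(n_ep) - 1 + round(window[1] * fs)  # sample offsets from onset
  t <- rel / fs
  onsets <- sort(raw$events$onset_s)
  keep <- logical(length(onsets))
  slices <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L                # 1-based onset sample
    idx <- i0 + rel
    if (idx[1] >= 1 && idx[length(idx)] <= n) {
      keep[i] <- TRUE
      slices[[i]] <- raw$data[, idx, drop = FALSE]
    }
  }
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(sprintf("%d event(s) too close to the recording edge; dropped", n_drop))
  slices <- slices[keep]
  if (!length(slices)) stop("no usable events remain after edge check")
  arr <- array(0, dim = c(length(slices), nrow(raw$data), n_ep))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  out <- epoched_data(arr, fs, t, raw$channel_labels, window, baseline_window,
                      n_dropped = n_drop)
  baseline_correct(out)
}

# subtract the per-epoch, per-channel scalar mean over the baseline window
baseline_correct <- function(epochs) {
  bl <- epochs$t >= epochs$baseline_window[1] &
        epochs$t < epochs$baseline_window[2]
  if (!any(bl)) stop("baseline window contains no samples")
  mns <- apply(epochs$data[, , bl, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(mns)  # recycles over 3rd dim
  epochs
}
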