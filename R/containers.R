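#' Raw continuous EEG recording
#'
#' Lightweight container for a continuous multichannel recording plus its
#' stimulus event table. Values are in microvolts.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate, Hz.
#' @param channel_labels character vector of 10-20 labels, one per row.
#' @param events data frame with columns `onset_s`, `duration_s`, `label`.
#' @return an object of class `"assr_raw"`.
#' @export
raw_recording <- function(data, fs, channel_labels, events = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop("'fs' must be positive")
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required")
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         label = character(0))
  events <- as.data.frame(events)
  req <- c("onset_s", "duration_s", "label")
  if (!all(req %in% names(events)))
    stop("'events' needs columns onset_s, duration_s, label")
  dur_s <- ncol(data) / fs
  if (nrow(events) && (any(events$onset_s < 0) || any(events$onset_s > dur_s)))
    stop("event onsets must lie within the recording")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "assr_raw")
}

#' @export
print.assr_raw <- function(x, ...) {
  cat(sprintf("<assr_raw> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Epoched EEG container
#'
#' Trials x channels x time array with a time axis relative to stimulus
#' onset. Constructed by [epoch_and_baseline()] or by the synthetic
#' generator; most users never call this directly.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs sampling rate, Hz.
#' @param t time axis in seconds relative to stimulus onset (length =
#'   dim 3 of `data`).
#' @param channel_labels channel names (length = dim 2).
#' @param window epoch window in seconds, half-open `[start, stop)`.
#' @param baseline_window baseline interval in seconds.
#' @param n_dropped number of events dropped at epoching (bookkeeping).
#' @return an object of class `"assr_epochs"`.
#' @export
epoched_data <- function(data, fs, t, channel_labels,
                         window = c(-1, 6), baseline_window = c(-0.5, -0.25),
                         n_dropped = 0L) {
  stopifnot(length(dim(data)) == 3)
  if (length(t) != dim(data)[3]) stop("time axis length must match data")
  if (length(channel_labels) != dim(data)[2])
    stop("channel label count must match data")
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
    stop("baseline window must lie inside the epoch window")
  structure(list(data = data, fs = fs, t = t,
                 channel_labels = as.character(channel_labels),
                 window = window, baseline_window = baseline_window,
                 t0_index = which.min(abs(t))[1],
                 n_dropped = n_dropped),
            class = "assr_epochs")
}

#' @export
print.assr_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<assr_epochs> %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2]))
  invisible(x)
}

#' Number of epochs / channels helpers
#' @param x an `"assr_epochs"` object.
#' @return integer count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' @rdname n_epochs
#' @export
n_channels <- function(x) dim(x$data)[2]

#' Select channels from an epoched container
#'
#' @param epochs an `"assr_epochs"` object.
#' @param channels character vector of labels to keep (order preserved
#'   as given).
#' @return a new `"assr_epochs"` with the selected channels.
#' @export
select_channels <- function(epochs, channels) {
  idx <- match(channels, epochs$channel_labels)
  if (anyNA(idx))
    stop("unknown channels: ", paste(channels[is.na(idx)], collapse = ", "))
  out <- epochs
  out$data <- epochs$data[, idx, , drop = FALSE]
  out$channel_labels <- epochs$channel_labels[idx]
  out
}

#' Scalp region channel sets
#'
#' Named channel selections used throughout the pipeline: the `mixed`
#' temporo-parietal/midline set that captures the auditory entrainment
#' response, the `frontal` set implicated in executive function, and
#' `whole` for all available channels.
#'
#' @param name one of `"mixed"`, `"frontal"`, `"whole"`.
#' @param available optional character vector restricting `"whole"`.
#' @return list with elements `name` and `channels`.
#' @export
region_selection <- function(name = c("mixed", "frontal", "whole"),
                             available = NULL) {
  name <- match.arg(name)
  channels <- switch(name,
    mixed = c("FT7", "T7", "TP7", "P7", "P5", "Fz", "FCz", "Cz", "CPz",
              "FT8", "T8", "TP8", "P6", "P8"),
    frontal = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    whole = available)
  if (name == "whole" && is.null(channels))
    stop("region 'whole' needs the available channel labels")
  list(name = name, channels = channels)
}
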