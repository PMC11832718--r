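#' Write / read a raw recording as TSV + JSON sidecar
#'
#' Portable plain-text serialization of a continuous recording: a
#' tab-separated sample matrix (one column per channel, microvolts), a
#' JSON sidecar with the sampling rate and channel labels, and the event
#' table as CSV. Round-trips through [read_raw_tsv()].
#'
#' @param raw an `"assr_raw"` recording.
#' @param path basename (without extension); writes `<path>.tsv`,
#'   `<path>.json` and `<path>_events.csv`.
#' @return `path`, invisibly.
#' @export
write_raw_tsv <- function(raw, path) {
  stopifnot(inherits(raw, "assr_raw"))
  m <- t(raw$data)
  colnames(m) <- raw$channel_labels
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(fs = raw$fs, channel_labels = raw$channel_labels,
                            n_samples = ncol(raw$data), unit = "uV"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write_events_csv(raw$events, paste0(path, "_events.csv"))
  invisible(path)
}

#' @rdname write_raw_tsv
#' @export
read_raw_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE)
  ev_path <- paste0(path, "_events.csv")
  events <- if (file.exists(ev_path)) read_events_csv(ev_path) else NULL
  raw_recording(t(as.matrix(m)), meta$fs, meta$channel_labels, events)
}

#' Event-table CSV I/O
#'
#' @param events data frame with `onset_s`, `duration_s`, `label`.
#' @param path CSV file path.
#' @return the events data frame (read) or `path` invisibly (write).
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- read.csv(path)
  req <- c("onset_s", "duration_s", "label")
  if (!all(req %in% names(ev)))
    stop("events CSV needs columns onset_s, duration_s, label")
  ev
}

#' Cognition-table CSV I/O
#'
#' @param table cognition data frame (see [simulate_cognition()]).
#' @param path CSV file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_cognition_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cognition_csv
#' @export
read_cognition_csv <- function(path) {
  tb <- read.csv(path)
  if (!all(c("id", "group") %in% names(tb)))
    stop("cognition CSV needs at least 'id' and 'group' columns")
  tb$group <- factor(tb$group)
  tb
}

#' Export a modulation profile as CSV
#'
#' @param profile an `"assr_modprofile"`.
#' @param path CSV file path; columns `t`, `am` and/or `itpc`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(t = profile$t)
  if (!is.null(profile$am)) df$am <- profile$am
  if (!is.null(profile$itpc)) df$itpc <- profile$itpc
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# small stable polynomial hash for provenance stamping (hex string);
# done in double arithmetic mod 2^32 to stay inside R's integer range
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
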