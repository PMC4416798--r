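#' Construct a multichannel EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (defaults to the canonical 64-channel
#'   order).
#' @param events data.frame with at least `onset_s`, `from_kmh`,
#'   `to_kmh` (may be empty). `onset_sample` is the time index
#'   `round(onset_s * fs)` (sample 0 is t = 0).
#' @param condition `"cued"`, `"uncued"` or NA.
#' @param session_id Integer session identifier.
#' @param profile Optional [render_speed_profile()] result.
#' @return An `eeg_recording` object.
#' @export
recording <- function(data, fs, labels = biosemi64_labels(),
                      events = NULL, condition = NA_character_,
                      session_id = NA_integer_, profile = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(labels))
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), from_kmh = numeric(0),
                         to_kmh = numeric(0))
  if (nrow(events) > 0 && is.null(events$onset_sample))
    events$onset_sample <- as.integer(round(events$onset_s * fs))
  structure(list(data = data, fs = fs, labels = labels, events = events,
                 condition = condition, session_id = session_id,
                 profile = profile),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %s, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              ifelse(is.na(x$condition), "?", x$condition), nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Write the event table of a recording as TSV
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @export
write_events_tsv <- function(rec, path) {
  ev <- rec$events
  out <- data.frame(onset_sample = ev$onset_sample, onset_s = ev$onset_s,
                    from_kmh = ev$from_kmh, to_kmh = ev$to_kmh)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events_tsv()]
#' @param path TSV path.
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a speed profile as TSV
#' @param profile A [render_speed_profile()] result.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(data.frame(t = profile$t, belt_ms = profile$belt,
                                rel_ms = profile$rel),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
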