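#' Construct a raw multichannel recording
#'
#' The basic in-memory container for a continuous EEG record: a channels
#' x time matrix in microvolts, channel labels, sampling rate, and task
#' events (prompt onsets with class labels).
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param channel_names Character vector, one unique label per row.
#' @param fs Sampling rate in Hz.
#' @param events Tibble/data.frame with columns `onset_sample` (1-based
#'   sample index of the task prompt) and `label` (e.g. `"left"`,
#'   `"right"`, `"rest"`). May be empty.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(samples, channel_names, fs,
                          events = tibble::tibble(onset_sample = integer(),
                                                  label = character())) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(channel_names), fs > 0)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names")
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    if (is.unsorted(events$onset_sample, strictly = TRUE))
      stop("event onsets must be strictly increasing")
    if (any(events$onset_sample < 1 | events$onset_sample > ncol(samples)))
      stop("event onsets outside the record")
  }
  structure(list(samples = samples,
                 channel_names = as.character(channel_names),
                 fs = fs, events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$events)))
  invisible(x)
}

#' Select channels from a recording
#'
#' @param raw A `raw_recording`.
#' @param channels Channel labels to keep, in the desired order.
#' @return A `raw_recording` containing exactly those channels.
#' @export
select_channels <- function(raw, channels) {
  idx <- match(channels, raw$channel_names)
  if (anyNA(idx))
    stop("channels not present in recording: ",
         paste(channels[is.na(idx)], collapse = ", "))
  raw_recording(raw$samples[idx, , drop = FALSE], channels, raw$fs, raw$events)
}
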