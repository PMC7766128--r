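#' Multichannel EEG recording container
#'
#' A light S3 container for a continuous recording: a channels-by-samples
#' numeric matrix (microvolts), channel labels, sampling rate, and an event
#' table with columns \code{onset_s}, \code{duration_s}, \code{label}.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channels character vector of channel labels (length nrow(data)).
#' @param fs sampling rate in Hz.
#' @param events data frame (onset_s, duration_s, label) or NULL.
#' @return object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, channels, fs, events = NULL) {
  data <- as.matrix(data)
  if (length(channels) != nrow(data))
    stop("channel labels (", length(channels),
         ") do not match data rows (", nrow(data), ")")
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         label = character(0), stringsAsFactors = FALSE)
  rownames(data) <- channels
  structure(list(data = data, channels = as.character(channels),
                 fs = fs, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1),
      " s), ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an \code{eeg_recording}.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Extract an epoch from a recording
#'
#' Cuts the half-open sample interval \code{[start_s, start_s + dur_s)}.
#'
#' @param rec an \code{eeg_recording}; @param start_s start time (s);
#' @param dur_s duration (s); @param label optional class label.
#' @return list with \code{data} (channels x samples), \code{fs},
#'   \code{label} -- the epoch structure consumed by the decoding stack.
#' @export
cut_epoch <- function(rec, start_s, dur_s, label = NA_character_) {
  i0 <- round(start_s * rec$fs) + 1
  i1 <- i0 + round(dur_s * rec$fs) - 1
  if (i0 < 1 || i1 > ncol(rec$data))
    stop("epoch [", start_s, ", ", start_s + dur_s, ") s outside recording")
  list(data = rec$data[, i0:i1, drop = FALSE], fs = rec$fs, label = label)
}
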