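## Minimal EDF (European Data Format) reader/writer for continuous EEG:
## ASCII fixed-width header, one-second data records of little-endian
## 16-bit integers, per-channel physical scaling.  Only the subset needed
## to round-trip this package's recordings is implemented.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width = 8) .edf_pad(formatC(x, format = "g",
                                                    digits = 7), width)

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits with symmetric per-channel physical
#' ranges; the recording is zero-padded to whole one-second data records.
#' Events are not embedded -- write them with [write_events()] alongside.
#'
#' @param rec an \code{eeg_recording}; @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_eeg <- function(rec, path) {
  ns <- length(rec$channels)
  spr <- as.integer(rec$fs)               # samples per 1 s record
  nrec <- ceiling(ncol(rec$data) / spr)
  dat <- rec$data
  if (ncol(dat) < nrec * spr)
    dat <- cbind(dat, matrix(0, ns, nrec * spr - ncol(dat)))
  pmax_ <- apply(abs(dat), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0001)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(.edf_pad("0", 8)); wr(.edf_pad("X", 80))
  wr(.edf_pad("synthetic EEG", 80))
  wr(.edf_pad("01.01.20", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256 * (ns + 1), 8)); wr(.edf_pad("", 44))
  wr(.edf_pad(nrec, 8)); wr(.edf_pad("1", 8)); wr(.edf_pad(ns, 4))
  for (ch in rec$channels) wr(.edf_pad(ch, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(.edf_num(-pmax_[i]))
  for (i in seq_len(ns)) wr(.edf_num(pmax_[i]))
  for (i in seq_len(ns)) wr(.edf_pad("-32767", 8))
  for (i in seq_len(ns)) wr(.edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(spr, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))
  scale <- pmax_ / 32767
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round(dat[, cols, drop = FALSE] / scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file; @param montage optional \code{montage_spec}: the
#'   channels are checked and reordered to montage order, and the sampling
#'   rate must match.
#' @param events_path optional companion events CSV (onset_s, duration_s,
#'   label); defaults to \code{<path>.events.csv} when that file exists.
#' @return an \code{eeg_recording}.
#' @export
read_eeg <- function(path, montage = NULL, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  fs <- spr / recdur
  if (length(unique(fs)) != 1)
    stop("mixed sampling rates are not supported")
  fs <- fs[1]
  dat <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (raw - dmin_[i]) *
        (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      dat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  if (!is.null(montage)) {
    if (fs != montage$sampling_rate)
      stop("file sampled at ", fs, " Hz but montage expects ",
           montage$sampling_rate, " Hz")
    missing <- setdiff(montage$channel_names, labels)
    if (length(missing))
      stop("file lacks montage channel(s): ", paste(missing, collapse = ", "))
    ord <- match(montage$channel_names, labels)
    dat <- dat[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  events <- NULL
  if (is.null(events_path)) {
    cand <- paste0(path, ".events.csv")
    if (file.exists(cand)) events_path <- cand
  }
  if (!is.null(events_path)) events <- read_events(events_path)
  eeg_recording(dat, labels, fs, events)
}

#' Write an event/trial table as CSV (onset_s, duration_s, label)
#' @param events data frame; @param path output CSV.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("onset_s", "duration_s", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an event/trial table CSV
#' @param path CSV with columns onset_s, duration_s, label.
#' @return data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ev)))
    stop("events file must have columns ", paste(need, collapse = ", "))
  ev[, need]
}

#' Convert an events table to the trial table used for training
#' @param events data frame (onset_s, duration_s, label).
#' @param fs sampling rate, for cue_sample.
#' @return trial table (trial, cue_s, cue_sample, duration_s, label).
#' @export
events_to_trials <- function(events, fs = 500) {
  data.frame(trial = seq_len(nrow(events)), cue_s = events$onset_s,
             cue_sample = round(events$onset_s * fs) + 1,
             duration_s = events$duration_s, label = events$label,
             stringsAsFactors = FALSE)
}
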