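## The two binary decoders (classifier_GvN: Gait MI vs Do-nothing,
## classifier_GvS: Gait MI vs Sit MI) and the real-time sliding-window
## decoding loop: 2 s processing window, 0.5 s shift, one hard command per
## shift at 500 Hz.

.label_to_command <- c(GAIT_MI = "GAIT", SIT_MI = "SIT", NOTHING = "NOTHING")

#' Canonical class pairs
#' @param pair "gvn" (Gait MI vs Do-nothing) or "gvs" (Gait MI vs Sit MI),
#'   or an explicit length-2 label vector.
#' @return length-2 character vector of class labels, Gait MI first.
#' @export
decoder_pair <- function(pair) {
  if (length(pair) == 2) return(as.character(pair))
  switch(tolower(pair),
         gvn = c("GAIT_MI", "NOTHING"),
         gvs = c("GAIT_MI", "SIT_MI"),
         stop("unknown pair '", pair, "' (use 'gvn' or 'gvs')"))
}

#' Cut labeled training windows from a session
#'
#' Cuts sliding analysis windows (2 s, 0.5 s shift by default) from within
#' each trial's engaged span: 1-9 s post-cue for the 8 s MI tasks and
#' 1-5 s for the 4 s Do-nothing task (1 s to 1 s + duration in general).
#' Each window inherits the trial's label; an \code{attr "trial"} vector
#' records the parent trial for leakage-free resampling.
#'
#' @param rec an \code{eeg_recording}; @param trials trial table from
#'   [generate_training_session()] (cue_s, duration_s, label);
#' @param pair optional class pair to restrict to; @param window_s,shift_s
#'   window geometry in seconds; @param span_offset_s engaged-span onset
#'   after the cue.
#' @return list of epochs, with \code{attr "trial"}.
#' @export
epoch_training_windows <- function(rec, trials, pair = NULL,
                                   window_s = 2, shift_s = 0.5,
                                   span_offset_s = 1) {
  if (!is.null(pair)) {
    pair <- decoder_pair(pair)
    trials <- trials[trials$label %in% pair, , drop = FALSE]
  }
  eps <- list(); trial_id <- integer(0)
  for (i in seq_len(nrow(trials))) {
    span0 <- trials$cue_s[i] + span_offset_s
    span1 <- span0 + trials$duration_s[i]
    if (span1 - span0 < window_s) {
      warning("trial ", trials$trial[i], " span shorter than the window; skipped")
      next
    }
    starts <- seq(span0, span1 - window_s, by = shift_s)
    for (s in starts) {
      eps[[length(eps) + 1]] <- cut_epoch(rec, s, window_s, trials$label[i])
      trial_id <- c(trial_id, trials$trial[i])
    }
  }
  attr(eps, "trial") <- trial_id
  eps
}

## fit selection + classifier on precomputed covariances (shared by
## train_decoder and the bootstrap evaluator)
train_from_covs <- function(fbc, labels, pair, k = 6,
                            pair_completion = TRUE, cost = 1,
                            shrinkage = 1e-4, idx = seq_along(labels)) {
  sub <- structure(list(covs = lapply(fbc$covs,
                                      function(a) a[, , idx, drop = FALSE]),
                        bank = fbc$bank), class = "fb_covs")
  lab <- labels[idx]
  fb <- fit_fbcsp_cov(sub, lab, pair, shrinkage = shrinkage)
  feats <- features_from_cov(sub, fb)
  ranking <- rank_features(feats, factor(lab, levels = pair))
  sel <- select_features(ranking, k, pair_completion)
  svm <- fit_linear_svm(feats[, sel$indices, drop = FALSE],
                        factor(lab, levels = pair), cost = cost)
  structure(list(fbcsp = fb, ranking = ranking, selection = sel, svm = svm,
                 pair = pair, k = k), class = "decoder_core")
}

predict_core <- function(core, fbc, idx = seq_len(dim(fbc$covs[[1]])[3])) {
  sub <- structure(list(covs = lapply(fbc$covs,
                                      function(a) a[, , idx, drop = FALSE]),
                        bank = fbc$bank), class = "fb_covs")
  feats <- features_from_cov(sub, core$fbcsp)
  predict_linear_svm(core$svm, feats[, core$selection$indices, drop = FALSE])
}

#' Train a binary motor-imagery decoder
#'
#' Full pipeline on sliding training windows: filter-bank CSP fit, feature
#' extraction, MIBIF ranking, top-k selection (with CSP pair completion)
#' and linear maximum-margin classification.
#'
#' @param rec session recording; @param trials trial table; @param pair
#'   class pair ("gvn", "gvs" or explicit labels); @param k number of
#'   MIBIF-selected features (nominally 4..10); @param bank filter bank;
#' @param pair_completion,cost,shrinkage pipeline settings;
#' @param window_s,shift_s decoding window geometry (2 s / 0.5 s).
#' @return object of class \code{decoder_model} (includes training
#'   accuracy over the training windows).
#' @export
train_decoder <- function(rec, trials, pair, k = 6, bank = filter_bank(),
                          pair_completion = TRUE, cost = 1,
                          shrinkage = 1e-4, window_s = 2, shift_s = 0.5) {
  pair <- decoder_pair(pair)
  wins <- epoch_training_windows(rec, trials, pair, window_s, shift_s)
  labels <- vapply(wins, `[[`, "", "label")
  if (any(table(factor(labels, levels = pair)) < 10))
    stop("need at least 10 training windows per class")
  fbc <- fb_covariances(wins, bank)
  core <- train_from_covs(fbc, labels, pair, k, pair_completion, cost,
                          shrinkage)
  train_acc <- mean(predict_core(core, fbc) == labels)
  structure(list(core = core, pair = pair, fs = rec$fs,
                 window_samples = round(window_s * rec$fs),
                 shift_samples = round(shift_s * rec$fs),
                 n_channels = nrow(rec$data),
                 training_accuracy = train_acc),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat("<decoder_model> ", paste(x$pair, collapse = " vs "), ", k=",
      x$core$k, ", window ", x$window_samples, "/shift ", x$shift_samples,
      " samples, training accuracy ",
      sprintf("%.1f%%", 100 * x$training_accuracy), "\n", sep = "")
  invisible(x)
}

#' Classify one decoding window
#'
#' @param window epoch of exactly \code{window_samples} samples (2 s).
#' @param model a \code{decoder_model}.
#' @return a command label: "GAIT", "SIT" or "NOTHING".
#' @export
classify_window <- function(window, model) {
  if (ncol(window$data) != model$window_samples)
    stop("window has ", ncol(window$data), " samples, expected ",
         model$window_samples)
  if (nrow(window$data) != model$n_channels)
    stop("window has ", nrow(window$data), " channels, expected ",
         model$n_channels)
  fbc <- fb_covariances(list(window), model$core$fbcsp$bank)
  lab <- predict_core(model$core, fbc)
  unname(.label_to_command[lab])
}

#' Split a recording into fixed-size stream packets
#'
#' @param rec an \code{eeg_recording}; @param packet_samples samples per
#'   packet (10 at 500 Hz, i.e. one packet every 20 ms).
#' @return list of packets: \code{list(seq, data)}; trailing samples that
#'   do not fill a packet are dropped.
#' @export
as_packets <- function(rec, packet_samples = 10) {
  np <- floor(ncol(rec$data) / packet_samples)
  lapply(seq_len(np), function(i)
    list(seq = i,
         data = rec$data[, ((i - 1) * packet_samples + 1):(i * packet_samples),
                         drop = FALSE]))
}

#' Decode a packetized stream in real-time geometry
#'
#' Accumulates packets into a ring buffer; once 2 s of signal has accrued
#' the decoder emits one command per 0.5 s of new data, each time-stamped
#' at its window end (first command at t = 2.0 s).  Output is identical to
#' offline classification of the same windows.
#'
#' @param x an \code{eeg_recording} or a list of packets from
#'   [as_packets()] (sequence numbers must be contiguous).
#' @param model a \code{decoder_model}.
#' @return data frame with \code{time_s} and \code{command}.
#' @export
stream_decode <- function(x, model) {
  if (inherits(x, "eeg_recording")) {
    dat <- x$data
  } else {
    seqs <- vapply(x, `[[`, 0, "seq")
    if (length(seqs) && any(diff(seqs) != 1))
      stop("packet sequence gap at packet ",
           seqs[which(diff(seqs) != 1)[1] + 1])
    dat <- do.call(cbind, lapply(x, `[[`, "data"))
  }
  n <- ncol(dat)
  w <- model$window_samples; s <- model$shift_samples
  ends <- if (n >= w) seq(w, n, by = s) else integer(0)
  if (!length(ends))
    return(data.frame(time_s = numeric(0), command = character(0),
                      stringsAsFactors = FALSE))
  if (nrow(dat) != model$n_channels)
    stop("stream has ", nrow(dat), " channels, model expects ",
         model$n_channels)
  ## batch the windows through the shared covariance path; identical to
  ## classify_window() on each window, just one filtering pass per chunk
  ## (chunked so long streams do not materialize every window at once)
  labs <- character(0)
  for (s0 in seq(1, length(ends), by = 200)) {
    sub <- ends[s0:min(length(ends), s0 + 199)]
    wins <- lapply(sub, function(e)
      list(data = dat[, (e - w + 1):e, drop = FALSE], fs = model$fs))
    fbc <- fb_covariances(wins, model$core$fbcsp$bank)
    labs <- c(labs, predict_core(model$core, fbc))
  }
  data.frame(time_s = ends / model$fs,
             command = unname(.label_to_command[labs]),
             stringsAsFactors = FALSE)
}
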