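## Quantitative evaluation: bootstrap offline accuracy (100 reps, 7:3
## train-test, 10 stratified test trials), online confusion rates
## (TPR/FPR/ACC), information transfer rate, Fisher-ratio topography,
## event-related spectral perturbation, and scenario timing.

#' Confusion-count rates
#'
#' TPR = nTP/(nTP+nFN), FPR = nFP/(nTN+nFP),
#' ACC = (nTP+nTN)/(nTP+nTN+nFP+nFN).  A zero denominator flags the
#' affected metric as NA rather than failing.
#'
#' @param counts list or vector with nTP, nTN, nFP, nFN (non-negative).
#' @return list with \code{TPR}, \code{FPR}, \code{ACC}.
#' @export
compute_rates <- function(counts) {
  cn <- c("nTP", "nTN", "nFP", "nFN")
  if (!all(cn %in% names(counts))) stop("counts must name nTP, nTN, nFP, nFN")
  v <- vapply(cn, function(k) as.numeric(counts[[k]]), 0)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  v <- unname(v)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  list(TPR = sdiv(v[1], v[1] + v[4]),
       FPR = sdiv(v[3], v[2] + v[3]),
       ACC = sdiv(v[1] + v[2], sum(v)))
}

#' Score emitted commands against a ground-truth intent timeline
#'
#' Each command is scored against the intent active at its window end
#' (positive class = Gait MI); commands outside any scored interval are
#' ignored.
#'
#' @param commands data frame (time_s, command); @param timeline an
#'   \code{intent_timeline}; @param pair decoder pair (determines which
#'   intents are scored and the negative label).
#' @return confusion-count list suitable for [compute_rates()].
#' @export
score_commands <- function(commands, timeline, pair) {
  pair <- decoder_pair(pair)
  neg_cmd <- unname(.label_to_command[pair[2]])
  counts <- c(nTP = 0L, nTN = 0L, nFP = 0L, nFN = 0L)
  for (i in seq_len(nrow(commands))) {
    t <- commands$time_s[i]
    hit <- timeline$label[timeline$start_s <= t & t < timeline$end_s &
                            timeline$label %in% pair]
    if (!length(hit)) next
    truth_pos <- hit[1] == pair[1]
    pred_pos <- commands$command[i] == "GAIT"
    if (!pred_pos && commands$command[i] != neg_cmd) next  # other decoder's label
    key <- if (truth_pos && pred_pos) "nTP" else if (truth_pos) "nFN"
    else if (pred_pos) "nFP" else "nTN"
    counts[key] <- counts[key] + 1L
  }
  as.list(counts)
}

#' Bit rate per decision (Wolpaw)
#'
#' \code{Id = log2(N) + p log2(p) + (1-p) log2((1-p)/(N-1))}, with the
#' p = 1 and p = 0 limits handled as 0 log 0 = 0.  Accuracies below chance
#' give a negative Id and a warning.
#'
#' @param p decoding accuracy in [0, 1]; @param N number of tasks (>= 2).
#' @return bits per trial.
#' @export
bit_rate <- function(p, N = 3) {
  if (N < 2) stop("N must be >= 2")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p < 1 / N) warning("accuracy below chance; bit rate is negative")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(N) + xlx(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (N - 1)), 0)
}

#' Information transfer rate
#' @param p accuracy; @param N task count; @param fd decision rate in
#'   trials/min (the study's printed averages: 4.60 offline, 5.97 online).
#' @return bits per minute (\code{fd * bit_rate(p, N)}).
#' @export
itr <- function(p, N = 3, fd = 4.60) {
  if (fd <= 0) stop("fd must be positive")
  fd * bit_rate(p, N)
}

#' Bootstrap offline accuracy of one decoder
#'
#' Replicates the offline evaluation protocol: per repetition, 10 test
#' trials are drawn at random (stratified, 5 per class); the training set
#' is drawn by bootstrap resampling (with replacement) from the remaining
#' trials; the full pipeline (filter-bank CSP, MIBIF, linear classifier)
#' is refit and each test trial is scored by majority vote over its
#' decoding windows (ties to the non-Gait class).  Band filtering and
#' covariance estimation are precomputed once per session -- they are
#' deterministic per window and identical across repetitions.
#'
#' @param rec session recording; @param trials trial table; @param pair
#'   class pair; @param reps repetitions (100); @param n_test test trials
#'   per rep (10, stratified); @param k,pair_completion,cost pipeline
#'   settings; @param seed RNG seed; @param permute_labels if TRUE,
#'   trial labels are randomly permuted first (chance-level control).
#' @return list with \code{mean}, \code{sd} (percent) and \code{per_rep}.
#' @export
bootstrap_offline_accuracy <- function(rec, trials, pair, reps = 100,
                                       n_test = 10, k = 6,
                                       pair_completion = TRUE, cost = 1,
                                       seed = 1, permute_labels = FALSE) {
  pair <- decoder_pair(pair)
  trials <- trials[trials$label %in% pair, , drop = FALSE]
  if (any(table(factor(trials$label, levels = pair)) < n_test / 2 + 2))
    stop("too few trials per class for the bootstrap protocol")
  wins <- epoch_training_windows(rec, trials, pair)
  win_trial <- attr(wins, "trial")
  labels <- vapply(wins, `[[`, "", "label")
  fbc <- fb_covariances(wins, filter_bank())
  trial_ids <- trials$trial
  trial_lab <- stats::setNames(trials$label, trials$trial)
  with_seed(seed, {
    if (permute_labels) {
      trial_lab[] <- sample(trial_lab)
      labels <- unname(trial_lab[as.character(win_trial)])
    }
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
      test_ids <- unlist(lapply(pair, function(cl)
        sample(trial_ids[trial_lab[as.character(trial_ids)] == cl],
               n_test / 2)))
      rest <- setdiff(trial_ids, test_ids)
      boot <- sample(rest, length(rest), replace = TRUE)
      tr_idx <- unlist(lapply(boot, function(id) which(win_trial == id)))
      core <- train_from_covs(fbc, labels, pair, k, pair_completion, cost,
                              idx = tr_idx)
      hits <- 0
      for (id in test_ids) {
        wi <- which(win_trial == id)
        pred <- predict_core(core, fbc, wi)
        vote_pos <- sum(pred == pair[1]) > length(pred) / 2
        truth_pos <- trial_lab[as.character(id)] == pair[1]
        hits <- hits + (vote_pos == truth_pos)
      }
      acc[r] <- 100 * hits / length(test_ids)
    }
    list(mean = mean(acc), sd = stats::sd(acc), per_rep = acc)
  })
}

#' Fisher-ratio topography
#'
#' Per channel and filter-bank band, the Fisher ratio
#' \code{(mu1 - mu2)^2 / (s1^2 + s2^2)} of trial log band powers between
#' the two classes; optionally normalized to [0, 1] over the map.
#'
#' @param rec session recording; @param trials trial table; @param pair
#'   class pair; @param bank filter bank; @param normalize logical.
#' @return channels x bands matrix (dimnames: channel names, band labels).
#' @export
fisher_ratio_map <- function(rec, trials, pair, bank = filter_bank(),
                             normalize = TRUE) {
  pair <- decoder_pair(pair)
  trials <- trials[trials$label %in% pair, , drop = FALSE]
  if (any(table(factor(trials$label, levels = pair)) < 2))
    stop("need at least 2 trials per class")
  eps <- lapply(seq_len(nrow(trials)), function(i)
    cut_epoch(rec, trials$cue_s[i] + 1,
              min(trials$duration_s[i], 4), trials$label[i]))
  nch <- nrow(rec$data); nb <- length(bank$bands)
  ## log band power per trial x channel x band via zero-phase filtering
  lp <- array(0, c(length(eps), nch, nb))
  for (b in seq_len(nb)) {
    flt <- butter_bandpass(bank$bands[[b]][1], bank$bands[[b]][2], rec$fs,
                           bank$order)
    for (i in seq_along(eps)) {
      xf <- filtfilt(t(eps[[i]]$data), flt)
      lp[i, , b] <- log(colMeans(xf^2))
    }
  }
  g1 <- trials$label == pair[1]
  fr <- matrix(NA_real_, nch, nb,
               dimnames = list(rec$channels,
                               vapply(bank$bands, function(b)
                                 paste0(b[1], "-", b[2], "Hz"), "")))
  for (c in seq_len(nch)) for (b in seq_len(nb)) {
    v <- stats::var(lp[g1, c, b]) + stats::var(lp[!g1, c, b])
    if (v > 0)
      fr[c, b] <- (mean(lp[g1, c, b]) - mean(lp[!g1, c, b]))^2 / v
  }
  if (normalize && any(is.finite(fr)) && max(fr, na.rm = TRUE) > 0)
    fr <- fr / max(fr, na.rm = TRUE)
  fr
}

#' Event-related spectral perturbation at one channel
#'
#' Morlet continuous-wavelet power (default 4-40 Hz, 6 cycles), averaged
#' over trials and expressed in dB relative to the whole-epoch mean power
#' of each frequency (cue at time 0 when epochs are cut at the cue).
#'
#' @param epochs list of equal-length epochs time-locked to the cue;
#' @param channel channel name or index; @param freqs analysis
#'   frequencies (Hz); @param n_cycles Morlet cycles; @param fs sampling
#'   rate (taken from the epochs).
#' @return list with \code{time_s}, \code{freqs}, \code{power_db}
#'   (freq x time matrix).
#' @export
ersp <- function(epochs, channel, freqs = 4:40, n_cycles = 6, fs = NULL) {
  if (is.null(fs)) fs <- epochs[[1]]$fs
  len <- unique(vapply(epochs, function(e) ncol(e$data), 0L))
  if (length(len) != 1) stop("all trials must have the same length")
  get_row <- function(e) {
    if (is.character(channel)) e$data[channel, ] else e$data[channel, ]
  }
  n <- len
  pow <- matrix(0, length(freqs), n)
  for (e in epochs) {
    x <- get_row(e)
    X <- stats::fft(c(x, rep(0, n)))      # zero-pad against wraparound
    for (fi in seq_along(freqs)) {
      f <- freqs[fi]
      sig <- n_cycles / (2 * pi * f)
      tt <- seq(-4 * sig, 4 * sig, by = 1 / fs)
      ker <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig^2))
      ker <- ker / sum(Mod(ker))
      K <- stats::fft(c(ker, rep(0 + 0i, 2 * n - length(ker))))
      conv <- stats::fft(X * K, inverse = TRUE) / (2 * n)
      half <- floor(length(tt) / 2)
      pow[fi, ] <- pow[fi, ] + Mod(conv[(half + 1):(half + n)])^2
    }
  }
  pow <- pow / length(epochs)
  base <- rowMeans(pow)
  list(time_s = seq(0, n - 1) / fs, freqs = freqs,
       power_db = 10 * log10(pow / base))
}

#' Scenario completion time and time ratio
#'
#' @param actions action table from [run_controller()] (column
#'   \code{time_s}); @param expected required action sequence (default:
#'   the full sit-to-sit scenario); @param reference_s reference
#'   completion time (s) for the ratio, or NA.
#' @param start_s scenario start time.
#' @return list with \code{completed}, \code{completion_s},
#'   \code{time_ratio_pct} (100 * t / reference).
#' @export
scenario_timing <- function(actions,
                            expected = c("STAND_UP", "GAIT_START",
                                         "GAIT_STOP", "GAIT_START",
                                         "GAIT_STOP", "SIT_DOWN"),
                            reference_s = NA, start_s = 0) {
  done <- identical(as.character(actions$action), as.character(expected))
  if (!done)
    return(list(completed = FALSE, completion_s = NA_real_,
                time_ratio_pct = NA_real_))
  ct <- max(actions$time_s) - start_s
  list(completed = TRUE, completion_s = ct,
       time_ratio_pct = if (is.na(reference_s)) NA_real_
       else 100 * ct / reference_s)
}
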