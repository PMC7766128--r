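# Evaluation: confusion rates, bit rate / ITR, Fisher maps, ERSP,
# scenario timing, controller completion under an imperfect decoder.

test_that("confusion rates reproduce hand-computed values", {
  r <- compute_rates(list(nTP = 10, nTN = 10, nFP = 0, nFN = 0))
  expect_equal(unlist(r), c(TPR = 1, FPR = 0, ACC = 1))
  r2 <- compute_rates(list(nTP = 8, nTN = 7, nFP = 3, nFN = 2))
  expect_equal(r2$TPR, 0.8)
  expect_equal(r2$FPR, 0.3)
  expect_equal(r2$ACC, 0.75)
  # zero denominators flag the metric, not the whole computation
  r3 <- compute_rates(list(nTP = 0, nTN = 5, nFP = 1, nFN = 0))
  expect_true(is.na(r3$TPR))
  expect_false(is.na(r3$FPR))
  expect_error(compute_rates(list(nTP = -1, nTN = 0, nFP = 0, nFN = 0)),
               "non-negative")
})

test_that("rates match a brute-force recount on random instances", {
  set.seed(30)
  for (i in 1:10) {
    truth <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    counts <- list(nTP = sum(pred & truth), nTN = sum(!pred & !truth),
                   nFP = sum(pred & !truth), nFN = sum(!pred & truth))
    r <- compute_rates(counts)
    expect_equal(r$ACC, mean(pred == truth))
    expect_equal(r$TPR, sum(pred & truth) / sum(truth))
    expect_equal(r$FPR, sum(pred & !truth) / sum(!truth))
  }
})

test_that("bit rate has the right limits, monotonicity and values", {
  expect_equal(bit_rate(1, 3), log2(3))
  expect_equal(bit_rate(1 / 3, 3), 0, tolerance = 1e-12)
  # closed form at p = 0.8
  p <- 0.8
  expect_equal(bit_rate(p, 3),
               log2(3) + p * log2(p) + (1 - p) * log2((1 - p) / 2))
  # continuous and increasing on [1/N, 1]
  grid <- seq(1 / 3, 1, length.out = 200)
  vals <- vapply(grid, bit_rate, 0, N = 3)
  expect_true(all(diff(vals) > 0))
  expect_warning(bit_rate(0.2, 3), "below chance")
  expect_error(bit_rate(1.2, 3), "p must be")
})

test_that("ITR is the bit rate scaled by the decision rate", {
  expect_equal(itr(1 / 3, 3, fd = 10), 0, tolerance = 1e-12)
  expect_equal(itr(0.85, 3, fd = 5.97), 5.97 * bit_rate(0.85, 3))
  expect_error(itr(0.8, 3, fd = 0), "positive")
})

test_that("command scoring aligns commands with the active intent", {
  tl <- intent_timeline(c(2, 10), c(6, 14), c("GAIT_MI", "NOTHING"))
  cmds <- data.frame(
    time_s = c(3, 4, 5, 11, 12, 13, 20),
    command = c("GAIT", "GAIT", "NOTHING", "NOTHING", "GAIT", "NOTHING",
                "GAIT"))
  counts <- score_commands(cmds, tl, "gvn")
  expect_equal(counts, list(nTP = 2L, nTN = 2L, nFP = 1L, nFN = 1L))
})

test_that("Fisher-ratio maps localize the simulated contrast", {
  # single Cz-weighted 10-12 Hz rhythm attenuated by Gait MI
  erd <- erd_params(
    oscillators = list(mu = list(channels = c(Cz = 1), band = c(10, 12),
                                 rms = 12)),
    depths = list(GAIT_MI = c(mu = 0.7), SIT_MI = c(), NOTHING = c()),
    background_rms = 3, line_amp = 1)
  ses <- generate_training_session(erd = erd, n_per_class = 5, seed = 55)
  fr <- fisher_ratio_map(ses$recording, ses$trials, "gvn")
  expect_equal(dim(fr), c(31, 6))
  idx <- which(fr == max(fr, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(rownames(fr)[idx[1]], "Cz")
  expect_equal(colnames(fr)[idx[2]], "10-12Hz")
  expect_lte(max(fr, na.rm = TRUE), 1)       # normalized
  # identical class distributions: the null map is far below the true map
  tr2 <- ses$trials[ses$trials$label == "NOTHING", ]
  tr2a <- tr2; tr2a$label <- rep(c("GAIT_MI", "NOTHING"),
                                 length.out = nrow(tr2a))
  tr2a$duration_s <- 4
  fr_true <- fisher_ratio_map(ses$recording, ses$trials, "gvn",
                              normalize = FALSE)
  fr2 <- fisher_ratio_map(ses$recording, tr2a, "gvn", normalize = FALSE)
  expect_lt(stats::median(fr2, na.rm = TRUE),
            max(fr_true, na.rm = TRUE) / 20)
  expect_error(fisher_ratio_map(ses$recording, tr2a[1:2, ], "gvn"),
               "2 trials")
})

test_that("ERSP is flat on stationary noise and shows the simulated ERD", {
  set.seed(56)
  # stationary noise: about 0 dB everywhere once the trial-averaged
  # chi-square fluctuation (~4.3/sqrt(n) dB per pixel) is small
  eps <- replicate(24, list(data = matrix(rnorm(31 * 2000), 31), fs = 500),
                   simplify = FALSE)
  er <- ersp(eps, channel = 15, freqs = seq(6, 30, by = 2))
  core <- er$power_db[, 300:1700]
  expect_lt(mean(abs(core)), 1)
  expect_lt(stats::quantile(abs(core), 0.99), 4)
  expect_lt(abs(mean(core)), 0.5)
  # doubling the amplitude leaves the dB map unchanged
  eps2 <- lapply(eps, function(e) { e$data <- 2 * e$data; e })
  er2 <- ersp(eps2, channel = 15, freqs = seq(6, 30, by = 2))
  expect_equal(er2$power_db, er$power_db, tolerance = 1e-9)
  # Gait-MI epochs: negative dB in the mu band during the engaged span
  ses <- small_session()
  tr <- ses$trials[ses$trials$label == "GAIT_MI", ]
  mi_eps <- lapply(seq_len(nrow(tr)), function(i)
    cut_epoch(ses$recording, tr$cue_s[i] - 1, 10))
  erm <- ersp(mi_eps, channel = "Cz", freqs = 8:20)
  mu <- erm$freqs >= 10 & erm$freqs <= 15
  engaged <- erm$time_s >= 3 & erm$time_s <= 9   # 2-8 s post-cue
  baseline_win <- erm$time_s <= 0.8
  expect_lt(mean(erm$power_db[mu, engaged]),
            mean(erm$power_db[mu, baseline_win]) - 3)
  # mismatched trial lengths rejected
  bad <- mi_eps; bad[[1]]$data <- bad[[1]]$data[, 1:100]
  expect_error(ersp(bad, channel = "Cz"), "same length")
})

test_that("scenario timing computes completion and the time ratio", {
  acts <- data.frame(
    time_s = c(20, 40, 60, 80, 100, 145),
    action = c("STAND_UP", "GAIT_START", "GAIT_STOP", "GAIT_START",
               "GAIT_STOP", "SIT_DOWN"))
  st <- scenario_timing(acts, reference_s = 100)
  expect_true(st$completed)
  expect_equal(st$completion_s, 145)
  expect_equal(st$time_ratio_pct, 145)
  st2 <- scenario_timing(acts[1:3, ], reference_s = 100)
  expect_false(st2$completed)
  expect_true(is.na(st2$time_ratio_pct))
})

test_that("an imperfect decoder still completes the scenario", {
  # pure-FSM simulation: commands are right with p = 0.85 at every tick;
  # the operator follows the scripted intent, pressing on until each
  # transition fires (scaled down to 20 seeded runs)
  set.seed(57)
  for (run in 1:20) {
    ctrl <- controller_init()
    actions <- character(0)
    phase <- 1   # 1 stand-up, 2 gait, 3 stop, 4 gait, 5 stop, 6 sit-down
    want <- list(c("TEB"), c("GAIT"), c("TEB"), c("GAIT"), c("TEB"),
                 c("TEB"), c("GAIT"), c("TEB"), c("TEB"), c("SIT"))
    step_i <- 1; ticks <- 0
    while (phase <= length(want) && ticks < 2000) {
      ticks <- ticks + 1
      intent <- want[[phase]]
      if (intent == "TEB") {
        inp <- teb
      } else {
        ok <- stats::runif(1) < 0.85
        other <- if (ctrl$state == "DECODE_GvN") "NOTHING" else
          setdiff(c("GAIT", "SIT"), intent)[1]
        inp <- cmd(if (ok) intent else other)
      }
      r <- fsm_step(ctrl, inp)
      ctrl <- r$state
      if (!is.na(r$action)) actions <- c(actions, r$action)
      # advance the script when the expected state change happened
      done <- switch(phase,
                     ctrl$state == "DECODE_GvN", ctrl$state == "STAND",
                     ctrl$state == "DECODE_GvS", ctrl$state == "GAIT",
                     ctrl$state == "STAND", ctrl$state == "DECODE_GvS",
                     ctrl$state == "GAIT", ctrl$state == "STAND",
                     ctrl$state == "DECODE_GvS", ctrl$state == "SIT")
      if (done) phase <- phase + 1
    }
    expect_equal(actions, c("STAND_UP", "GAIT_START", "GAIT_STOP",
                            "GAIT_START", "GAIT_STOP", "SIT_DOWN"))
    expect_equal(ctrl$state, "SIT")
  }
})
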