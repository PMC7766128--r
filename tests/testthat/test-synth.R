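# Synthetic EEG generator: session structure, determinism, ERD depth,
# blink injection, scenario streams.

test_that("montage and recording containers validate their invariants", {
  m <- default_montage()
  expect_length(m$channel_names, 31)
  expect_false(anyDuplicated(m$channel_names) > 0)
  expect_identical(m$channel_names[c(1, 2, 15)], c("FP1", "FP2", "Cz"))
  expect_error(montage_spec(c("A", "A")), "unique")
  expect_error(montage_spec(sampling_rate = -1), "sampling_rate")
  expect_error(montage_spec("NOPE"), "coordinates")
  expect_error(eeg_recording(matrix(0, 2, 10), "one", 500), "labels")
  rec <- eeg_recording(matrix(rnorm(62), 31, 2), m$channel_names, 500)
  expect_error(cut_epoch(rec, 0, 1), "outside")
})

test_that("a training session has the protocol's trial structure", {
  ses <- small_session()
  expect_equal(nrow(ses$trials), 18)
  expect_equal(as.integer(table(ses$trials$label)), rep(6L, 3))
  expect_equal(unique(ses$trials$duration_s[ses$trials$label != "NOTHING"]), 8)
  expect_equal(unique(ses$trials$duration_s[ses$trials$label == "NOTHING"]), 4)
  # pre-cue fixation between 3 and 5 s (first trial measures it directly)
  expect_gte(ses$trials$cue_s[1], 3)
  expect_lte(ses$trials$cue_s[1], 5)
  gaps <- diff(ses$trials$cue_s) -
    (head(ses$trials$duration_s, -1))
  expect_true(all(gaps >= 3 + 2 & gaps <= 5 + 2))   # fixation + fixed gap
  expect_equal(nrow(ses$recording$events), 18)
})

test_that("a minimal session is valid and long enough", {
  ses <- generate_training_session(n_per_class = 1, seed = 1)
  expect_equal(nrow(ses$trials), 3)
  expect_gte(recording_duration(ses$recording), 3 + 8 + 3 + 8 + 3 + 4)
  expect_error(generate_training_session(n_per_class = 0), "n_per_class")
})

test_that("identical seeds give bit-identical sessions", {
  a <- generate_training_session(n_per_class = 1, seed = 99)
  b <- generate_training_session(n_per_class = 1, seed = 99)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$trials, b$trials)
  c <- generate_training_session(n_per_class = 1, seed = 100)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("ERD attenuates band power by the configured depth", {
  # one midline oscillator, nearly clean background, long intervals
  erd <- erd_params(
    oscillators = list(mu = list(channels = c(Cz = 1), band = c(10, 15),
                                 rms = 12)),
    depths = list(GAIT_MI = c(mu = 0.6), SIT_MI = c(), NOTHING = c()),
    background_rms = 1, line_amp = 0)
  sc <- intent_timeline(c(5, 50), c(40, 85),
                        c("GAIT_MI", "NOTHING"))
  st <- generate_scenario_stream(erd = erd, script = sc, seed = 8)
  cz <- st$recording$data["Cz", ]
  p_mi <- band_power(cz[(10 * 500):(35 * 500)], 500, c(10, 15))
  p_rest <- band_power(cz[(55 * 500):(80 * 500)], 500, c(10, 15))
  ratio <- p_mi / p_rest
  expect_lt(abs(ratio - 0.16), 0.2 * 0.16 + 0.02)   # (1-depth)^2 within 20%
})

test_that("erd_params validates depths, bands and weights", {
  expect_error(erd_params(depths = list(GAIT_MI = c(mu_mid = 1.5),
                                        SIT_MI = c(), NOTHING = c())),
               "depth")
  bad <- list(mu = list(channels = c(Cz = 1), band = c(2, 5), rms = 10))
  expect_error(erd_params(oscillators = bad), "7-34")
  bad2 <- list(mu = list(channels = c(Cz = -1), band = c(10, 12), rms = 10))
  expect_error(erd_params(oscillators = bad2), ">= 0")
})

test_that("blink injection is additive, frontal-dominant and local", {
  rec <- noise_recording()
  bp <- blink_params()
  pre_max <- max(rec$data["FP1", (0.8 * 500):(1.4 * 500)])
  rec2 <- inject_blinks(rec, 1.0, bp)
  seg <- rec2$data["FP1", (0.9 * 500):(1.4 * 500)]
  expect_gt(max(seg), pre_max)
  expect_gt(max(seg), 0.8 * bp$amplitude)
  # untouched outside the pulse support
  expect_identical(rec2$data[, 1:400], rec$data[, 1:400])
  # falloff 0: only the prefrontal pair is modified
  rec3 <- inject_blinks(rec, 1.0, blink_params(falloff = 0))
  others <- setdiff(rec$channels, c("FP1", "FP2"))
  expect_identical(rec3$data[others, ], rec$data[others, ])
  expect_false(identical(rec3$data["FP1", ], rec$data["FP1", ]))
  # occipital band power unchanged when falloff excludes them
  expect_equal(band_power(rec3$data["Oz", ], 500, c(8, 30)),
               band_power(rec$data["Oz", ], 500, c(8, 30)))
  # overlapping pulses sum; out-of-range rejected
  expect_silent(inject_blinks(rec, c(2, 2.05), bp))
  expect_error(inject_blinks(rec, recording_duration(rec) + 1, bp),
               "outside")
})

test_that("a triple blink yields three local envelope maxima", {
  rec <- inject_blinks(noise_recording(), c(10, 10.35, 10.7), blink_params())
  env <- frontal_preprocess(rec)
  thr <- calibrate_threshold(noise_recording())
  win <- env[(9.8 * 500):(11.4 * 500)]   # a 1.6 s window covering all three
  expect_equal(as.integer(count_peaks(win, thr, 500)), 3L)
})

test_that("blink parameter invariants hold", {
  expect_error(blink_params(gap_s = 0.7), "1.6 s")
  expect_error(blink_params(amplitude = -5), "invalid")
})

test_that("scenario streams realize their scripts", {
  # empty script: background only, no events
  st0 <- generate_scenario_stream(script = intent_timeline(), seed = 3,
                                  duration_s = 12)
  expect_equal(nrow(st0$recording$events), 0)
  expect_equal(recording_duration(st0$recording), 12)
  # a lone 1.6 s TEB interval carries exactly 3 pulses above 5x noise RMS
  sc <- intent_timeline(5, 6.6, "TEB")
  st <- generate_scenario_stream(script = sc, seed = 4, duration_s = 20)
  fp1 <- st$recording$data["FP1", (4.5 * 500):(7.5 * 500)]
  cnt <- count_peaks(abs(fp1), 5 * 10, 500, min_gap_s = 0.2)
  expect_equal(as.integer(cnt), 3L)
  expect_identical(st$timeline, sc)
  # TEB interval shorter than the triple span is rejected
  expect_error(generate_scenario_stream(
    script = intent_timeline(5, 5.5, "TEB"), seed = 1), "triple-blink")
})

test_that("the default gait scenario has enough MI and TEB intervals", {
  sc <- default_gait_scenario()
  expect_gte(sum(sc$label %in% c("GAIT_MI", "SIT_MI")), 4)
  expect_gte(sum(sc$label == "TEB"), 3)
})

test_that("random blink scripts have the requested composition", {
  sc <- random_blink_script(5, 8, 3, seed = 2)
  expect_equal(as.integer(table(factor(sc$label,
                                       c("TEB", "SINGLE_BLINK",
                                         "DOUBLE_BLINK")))), c(5L, 8L, 3L))
  expect_true(all(diff(sc$start_s) > 0))
  expect_true(all(sc$start_s[-1] - sc$end_s[-nrow(sc)] >= 3))
  expect_identical(sc, random_blink_script(5, 8, 3, seed = 2))
})

test_that("intent timelines reject malformed intervals", {
  expect_error(intent_timeline(5, 4, "TEB"), "start < end")
  expect_error(intent_timeline(1, 2, "WAT"), "unknown")
  expect_error(intent_timeline(c(1, 5), c(10, 8),
                               c("GAIT_MI", "SIT_MI")), "overlap")
})
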