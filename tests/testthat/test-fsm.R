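# Controller: buffer dynamics, state transitions, full scenario traces,
# safety properties.

test_that("buffer updates fill by one, empty by three, and clamp", {
  cfg <- fsm_config()
  lvl <- 0
  for (i in 1:10) lvl <- buffer_update(lvl, "FILL", cfg)
  expect_equal(lvl, 10)
  expect_equal(buffer_update(10, "FILL", cfg), 10)
  expect_equal(buffer_update(5, "EMPTY", cfg), 2)
  expect_equal(buffer_update(0, "EMPTY", cfg), 0)
  expect_equal(buffer_update(2, "EMPTY", cfg), 0)
  # the inverse 3:1 reading is available by configuration
  cfg2 <- fsm_config(fill = 3, empty = -1)
  expect_equal(buffer_update(0, "FILL", cfg2), 3)
  expect_equal(buffer_update(3, "EMPTY", cfg2), 2)
})

test_that("single steps follow the machine's transition rules", {
  ctrl <- controller_init()
  expect_equal(ctrl$state, "SIT")
  # SIT + TEB -> DECODE_GvN, no action
  r <- fsm_step(ctrl, teb)
  expect_equal(r$state$state, "DECODE_GvN")
  expect_true(is.na(r$action))
  # commands outside decoder states are ignored
  r2 <- fsm_step(ctrl, cmd("GAIT"))
  expect_equal(r2$state$state, "SIT")
  expect_true(is.na(r2$action))
  # DECODE_GvS with stand_to_gait at 9 + GAIT -> GAIT_START
  ctrl3 <- controller_init()
  ctrl3$state <- "DECODE_GvS"; ctrl3$stand_to_gait <- 9L
  r3 <- fsm_step(ctrl3, cmd("GAIT"))
  expect_equal(r3$action, "GAIT_START")
  expect_equal(r3$state$state, "GAIT")
  expect_equal(r3$state$stand_to_gait, 0L)     # buffers reset on entry
  # GAIT + GAIT command: recurrent arrow, no change
  ctrl4 <- controller_init(); ctrl4$state <- "GAIT"
  r4 <- fsm_step(ctrl4, cmd("GAIT"))
  expect_equal(r4$state$state, "GAIT")
  expect_true(is.na(r4$action))
  # GAIT + TEB -> GAIT_STOP back to STAND
  r5 <- fsm_step(ctrl4, teb)
  expect_equal(r5$action, "GAIT_STOP")
  expect_equal(r5$state$state, "STAND")
  # GvS: GAIT fills stand_to_gait and empties stand_to_sit, vice versa
  ctrl6 <- controller_init(); ctrl6$state <- "DECODE_GvS"
  ctrl6$stand_to_sit <- 5L
  r6 <- fsm_step(ctrl6, cmd("GAIT"))
  expect_equal(r6$state$stand_to_gait, 1L)
  expect_equal(r6$state$stand_to_sit, 2L)
  # malformed input rejected
  expect_error(fsm_step(ctrl, list(type = "CMD", label = "JUMP")),
               "label")
  expect_error(fsm_step(ctrl, list(foo = 1)), "input")
})

test_that("the perfect-input scenario produces the canonical action list", {
  seq_inputs <- c(list(teb), rep(list(cmd("GAIT")), 10),
                  list(teb), rep(list(cmd("GAIT")), 10),
                  list(teb),
                  list(teb), rep(list(cmd("GAIT")), 10),
                  list(teb),
                  list(teb), rep(list(cmd("SIT")), 10))
  inputs <- data.frame(
    time_s = seq_along(seq_inputs) * 0.5,
    type = vapply(seq_inputs, `[[`, "", "type"),
    label = vapply(seq_inputs, function(i)
      if (is.null(i$label)) NA_character_ else i$label, ""),
    stringsAsFactors = FALSE)
  res <- run_controller(inputs)
  expect_equal(res$actions$action,
               c("STAND_UP", "GAIT_START", "GAIT_STOP", "GAIT_START",
                 "GAIT_STOP", "SIT_DOWN"))
  expect_equal(res$final_state, "SIT")
  # determinism: identical inputs, identical logs
  expect_identical(run_controller(inputs)$trace, res$trace)
  # empty input: no actions, still SIT
  r0 <- run_controller(inputs[0, ])
  expect_equal(nrow(r0$actions), 0)
  expect_equal(r0$final_state, "SIT")
  # unsorted input rejected
  bad <- inputs; bad$time_s <- rev(bad$time_s)
  expect_error(run_controller(bad), "sorted")
})

test_that("alternating fill/empty never accumulates under the 1:3 ratio", {
  inputs <- data.frame(
    time_s = (1:100) * 0.5,
    type = "CMD",
    label = rep(c("GAIT", "NOTHING"), 50),
    stringsAsFactors = FALSE)
  inputs <- rbind(data.frame(time_s = 0, type = "TEB",
                             label = NA_character_), inputs)
  res <- run_controller(inputs)
  expect_equal(nrow(res$actions), 0)
  expect_lte(max(res$trace$sit_to_stand), 1)
})

test_that("fuzzed input streams never violate the safety invariants", {
  set.seed(77)
  labels <- c("GAIT", "SIT", "NOTHING")
  for (run in 1:5) {
    n <- 400
    is_teb <- stats::runif(n) < 0.08
    inputs <- data.frame(
      time_s = cumsum(stats::runif(n, 0.1, 1)),
      type = ifelse(is_teb, "TEB", "CMD"),
      label = ifelse(is_teb, NA_character_,
                     sample(labels, n, replace = TRUE)),
      stringsAsFactors = FALSE)
    res <- run_controller(inputs)
    tr <- res$trace
    lv <- c(tr$sit_to_stand, tr$stand_to_gait, tr$stand_to_sit)
    expect_true(all(lv >= 0 & lv <= 10))
    # actions only out of decoder states or a TEB while walking
    acts <- tr[tr$action != "", ]
    if (nrow(acts)) {
      expect_true(all(
        (acts$action == "STAND_UP" & acts$state == "STAND") |
          (acts$action == "GAIT_START" & acts$state == "GAIT") |
          (acts$action == "GAIT_STOP" & acts$state == "STAND") |
          (acts$action == "SIT_DOWN" & acts$state == "SIT")))
    }
    # a STAND_UP requires ten net fills: never from a single command after
    # any state entry (buffer must have reached capacity)
    i_up <- which(tr$action == "STAND_UP")
    for (i in i_up) {
      expect_gte(i, 10)   # at least ten inputs must precede it
    }
  }
})

test_that("a single false GAIT command cannot stand the robot up", {
  ctrl <- controller_init()
  ctrl <- fsm_step(ctrl, teb)$state           # DECODE_GvN, buffers empty
  for (lvl in 0:8) {
    ctrl$sit_to_stand <- as.integer(lvl)
    r <- fsm_step(ctrl, cmd("GAIT"))
    expect_true(is.na(r$action))
  }
  ctrl$sit_to_stand <- 9L
  expect_equal(fsm_step(ctrl, cmd("GAIT"))$action, "STAND_UP")
})
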