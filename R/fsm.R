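## Asynchronous exoskeleton controller: a five-state machine (SIT,
## DECODE_GvN, STAND, DECODE_GvS, GAIT) gated by the TEB switch, with
## three size-10 command stack buffers and 1:3 fill/empty dynamics.  A
## state transition that moves the robot fires only on a full buffer (or a
## TEB while walking), so a single false classification can never actuate.

.fsm_states <- c("SIT", "DECODE_GvN", "STAND", "DECODE_GvS", "GAIT")
.fsm_actions <- c("STAND_UP", "GAIT_START", "GAIT_STOP", "SIT_DOWN")

#' Controller configuration
#'
#' @param capacity buffer size (10).
#' @param fill,empty level change of a filling / emptying command (+1 and
#'   -3: the 1:3 ratio, so one false command must be outweighed by three
#'   correct ones; set \code{fill = 3, empty = -1} for the inverse
#'   reading).
#' @param gait_stop_by_teb if TRUE (default) a TEB while walking stops the
#'   gait; the alternative reading routes gait stop through the decoder.
#' @param reset_on_entry reset all buffers to zero whenever a state is
#'   entered.
#' @return object of class \code{fsm_config}.
#' @export
fsm_config <- function(capacity = 10, fill = 1, empty = -3,
                       gait_stop_by_teb = TRUE, reset_on_entry = TRUE) {
  stopifnot(capacity >= 1, fill >= 1, empty <= -1)
  structure(list(capacity = capacity, fill = fill, empty = empty,
                 gait_stop_by_teb = gait_stop_by_teb,
                 reset_on_entry = reset_on_entry),
            class = "fsm_config")
}

#' Initial controller state
#'
#' The system starts (and may only terminate) in SIT with empty buffers.
#' @param config an \code{fsm_config}.
#' @return object of class \code{controller_state} with fields
#'   \code{state} and the three buffer levels \code{sit_to_stand},
#'   \code{stand_to_gait}, \code{stand_to_sit}.
#' @export
controller_init <- function(config = fsm_config()) {
  structure(list(state = "SIT", sit_to_stand = 0L, stand_to_gait = 0L,
                 stand_to_sit = 0L, config = config),
            class = "controller_state")
}

#' Update one command buffer
#'
#' FILL adds the fill step, EMPTY subtracts the empty magnitude; levels
#' clamp to [0, capacity].
#'
#' @param level current level; @param event "FILL" or "EMPTY";
#' @param config an \code{fsm_config}.
#' @return new level.
#' @export
buffer_update <- function(level, event = c("FILL", "EMPTY"),
                          config = fsm_config()) {
  event <- match.arg(event)
  step <- if (event == "FILL") config$fill else config$empty
  max(0L, min(config$capacity, as.integer(level + step)))
}

.reset_buffers <- function(ctrl) {
  if (ctrl$config$reset_on_entry)
    ctrl[c("sit_to_stand", "stand_to_gait", "stand_to_sit")] <- 0L
  ctrl
}

#' One controller step
#'
#' Applies a single input -- a TEB event (\code{list(type = "TEB")}) or a
#' decoder command (\code{list(type = "CMD", label = "GAIT"/"SIT"/
#' "NOTHING")}) -- to the controller.  Unlisted (state, input) pairs leave
#' the state unchanged; commands are ignored outside the two decoder
#' states.
#'
#' @param ctrl a \code{controller_state}; @param input see above.
#' @return list with \code{state} (new \code{controller_state}) and
#'   \code{action} (one of STAND_UP, GAIT_START, GAIT_STOP, SIT_DOWN, or
#'   NA).
#' @export
fsm_step <- function(ctrl, input) {
  if (!is.list(input) || is.null(input$type) ||
      !input$type %in% c("TEB", "CMD"))
    stop("input must be list(type = 'TEB') or list(type = 'CMD', label = ...)")
  if (input$type == "CMD" &&
      (is.null(input$label) || !input$label %in% c("GAIT", "SIT", "NOTHING")))
    stop("command label must be GAIT, SIT or NOTHING")
  cfg <- ctrl$config
  action <- NA_character_
  if (input$type == "TEB") {
    if (ctrl$state == "SIT") {
      ctrl$state <- "DECODE_GvN"; ctrl <- .reset_buffers(ctrl)
    } else if (ctrl$state == "STAND") {
      ctrl$state <- "DECODE_GvS"; ctrl <- .reset_buffers(ctrl)
    } else if (ctrl$state == "GAIT" && cfg$gait_stop_by_teb) {
      ctrl$state <- "STAND"; ctrl <- .reset_buffers(ctrl)
      action <- "GAIT_STOP"
    }
  } else if (ctrl$state == "DECODE_GvN") {
    ev <- if (input$label == "GAIT") "FILL" else "EMPTY"
    ctrl$sit_to_stand <- buffer_update(ctrl$sit_to_stand, ev, cfg)
    if (ctrl$sit_to_stand >= cfg$capacity) {
      ctrl$state <- "STAND"; ctrl <- .reset_buffers(ctrl)
      action <- "STAND_UP"
    }
  } else if (ctrl$state == "DECODE_GvS") {
    if (input$label == "GAIT") {
      ctrl$stand_to_gait <- buffer_update(ctrl$stand_to_gait, "FILL", cfg)
      ctrl$stand_to_sit <- buffer_update(ctrl$stand_to_sit, "EMPTY", cfg)
    } else if (input$label == "SIT") {
      ctrl$stand_to_sit <- buffer_update(ctrl$stand_to_sit, "FILL", cfg)
      ctrl$stand_to_gait <- buffer_update(ctrl$stand_to_gait, "EMPTY", cfg)
    }
    if (ctrl$stand_to_gait >= cfg$capacity) {
      ctrl$state <- "GAIT"; ctrl <- .reset_buffers(ctrl)
      action <- "GAIT_START"
    } else if (ctrl$stand_to_sit >= cfg$capacity) {
      ctrl$state <- "SIT"; ctrl <- .reset_buffers(ctrl)
      action <- "SIT_DOWN"
    }
  }
  list(state = ctrl, action = action)
}

#' Run the controller over a merged input sequence
#'
#' Folds [fsm_step()] over time-sorted inputs and logs every step: state,
#' buffer trajectory and emitted actions.
#'
#' @param inputs data frame with columns \code{time_s}, \code{type}
#'   ("TEB"/"CMD") and \code{label} (command label or NA), sorted by time.
#' @param config an \code{fsm_config}.
#' @return list with \code{trace} (one row per input: time, input, state
#'   after the step, buffer levels, action) and \code{actions} (rows with
#'   an emitted action).
#' @export
run_controller <- function(inputs, config = fsm_config()) {
  if (nrow(inputs) && is.unsorted(inputs$time_s))
    stop("controller inputs must be sorted by time")
  ctrl <- controller_init(config)
  n <- nrow(inputs)
  trace <- data.frame(
    time_s = numeric(n), input = character(n), state = character(n),
    sit_to_stand = integer(n), stand_to_gait = integer(n),
    stand_to_sit = integer(n), action = character(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    input <- list(type = inputs$type[i])
    if (input$type == "CMD") input$label <- inputs$label[i]
    res <- fsm_step(ctrl, input)
    ctrl <- res$state
    trace[i, ] <- list(inputs$time_s[i],
                       if (input$type == "TEB") "TEB" else input$label,
                       ctrl$state, ctrl$sit_to_stand, ctrl$stand_to_gait,
                       ctrl$stand_to_sit,
                       if (is.na(res$action)) "" else res$action)
  }
  list(trace = trace, actions = trace[trace$action != "", , drop = FALSE],
       final_state = ctrl$state)
}

#' Merge decoder commands and TEB events into a controller input table
#'
#' Commands emitted while the controller is not in a decoder state are
#' still listed (the FSM ignores them); inputs are interleaved by
#' timestamp, TEB events first on ties.
#'
#' @param commands data frame (time_s, command) from [stream_decode()].
#' @param teb_events data frame (time_s, ...) from [detect_teb()].
#' @return sorted data frame (time_s, type, label).
#' @export
merge_controller_inputs <- function(commands, teb_events) {
  a <- data.frame(time_s = teb_events$time_s, type = "TEB",
                  label = NA_character_, stringsAsFactors = FALSE)
  b <- data.frame(time_s = commands$time_s, type = "CMD",
                  label = commands$command, stringsAsFactors = FALSE)
  out <- rbind(a, b)
  out[order(out$time_s, out$type != "TEB"), , drop = FALSE]
}
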