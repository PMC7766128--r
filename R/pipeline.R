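## End-to-end online pipeline: TEB switch + the two decoders + the FSM,
## replayed over a (synthetic or recorded) scenario stream.

#' Run the full hybrid controller over a scenario stream
#'
#' Decodes the stream with both binary classifiers on the 2 s / 0.5 s
#' grid, detects triple eye-blinks, and folds the finite-state machine
#' over the merged event sequence.  At each decoding tick the command of
#' the classifier belonging to the current decoder state is consumed
#' (classifier_GvN in DECODE_GvN, classifier_GvS in DECODE_GvS); commands
#' arriving in any other state are ignored, as in the online system.
#'
#' @param rec scenario stream (\code{eeg_recording});
#' @param model_gvn,model_gvs trained \code{decoder_model}s;
#' @param threshold calibrated TEB threshold;
#' @param teb_config a \code{blink_detector_config};
#' @param fsm_cfg an \code{fsm_config}.
#' @return list: \code{trace}, \code{actions}, \code{final_state},
#'   \code{teb_events}, \code{commands_gvn}, \code{commands_gvs}.
#' @export
run_scenario <- function(rec, model_gvn, model_gvs, threshold,
                         teb_config = blink_detector_config(),
                         fsm_cfg = fsm_config()) {
  cmds_gvn <- stream_decode(rec, model_gvn)
  cmds_gvs <- stream_decode(rec, model_gvs)
  teb <- detect_teb(rec, threshold, teb_config)
  ev <- rbind(data.frame(time_s = teb$time_s, type = "TEB",
                         stringsAsFactors = FALSE),
              data.frame(time_s = cmds_gvn$time_s, type = "TICK",
                         stringsAsFactors = FALSE))
  ev <- ev[order(ev$time_s, ev$type != "TEB"), , drop = FALSE]
  ctrl <- controller_init(fsm_cfg)
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    t <- ev$time_s[i]
    if (ev$type[i] == "TEB") {
      input <- list(type = "TEB"); shown <- "TEB"
    } else {
      cmd <- switch(ctrl$state,
                    DECODE_GvN = cmds_gvn$command[cmds_gvn$time_s == t],
                    DECODE_GvS = cmds_gvs$command[cmds_gvs$time_s == t],
                    NULL)
      if (!length(cmd)) next
      input <- list(type = "CMD", label = cmd); shown <- cmd
    }
    res <- fsm_step(ctrl, input)
    ctrl <- res$state
    rows[[length(rows) + 1]] <- data.frame(
      time_s = t, input = shown, state = ctrl$state,
      sit_to_stand = ctrl$sit_to_stand,
      stand_to_gait = ctrl$stand_to_gait,
      stand_to_sit = ctrl$stand_to_sit,
      action = if (is.na(res$action)) "" else res$action,
      stringsAsFactors = FALSE)
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), input = character(0),
               state = character(0), sit_to_stand = integer(0),
               stand_to_gait = integer(0), stand_to_sit = integer(0),
               action = character(0), stringsAsFactors = FALSE)
  list(trace = trace, actions = trace[trace$action != "", , drop = FALSE],
       final_state = ctrl$state, teb_events = teb,
       commands_gvn = cmds_gvn, commands_gvs = cmds_gvs)
}
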