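## Synthetic EEG: seeded sessions and scenario streams with ground truth.
##
## The generator states a concrete "world": band-limited sensorimotor
## rhythms over the motor strip whose amplitude is attenuated (ERD) during
## motor-imagery intervals with class-distinct spatial/spectral signatures,
## per-channel pink background noise, a common-mode 60 Hz line component,
## and stereotyped biphasic eye-blink pulses dominant at FP1/FP2.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global random stream so seeded generation does not
#' perturb the caller's RNG state.
#' @param seed integer seed; @param expr expression to evaluate.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sensorimotor-rhythm / ERD parameters of the synthetic world
#'
#' Defines the resting rhythms (spatial weight map, frequency band, RMS
#' amplitude) and, per motor-imagery class, the fractional amplitude
#' attenuation (ERD depth) each rhythm undergoes while that class is
#' engaged.  Defaults give Gait MI a midline mu-band (10-15 Hz) signature
#' and Sit MI a broader centro-parietal mu plus a 21-25 Hz beta component,
#' so the two MI classes are spatially and spectrally separable.
#'
#' @param oscillators list of rhythms; each a list with \code{channels}
#'   (named non-negative weights), \code{band} (c(low, high) Hz within
#'   7-34 Hz), \code{rms} (resting RMS amplitude, microvolts).
#' @param depths per-class named list mapping oscillator name to ERD depth
#'   in [0, 1] (fraction of amplitude removed during MI).
#' @param onset_ramp_s linear ramp length of the attenuation at interval
#'   edges (s), emulating the gradual build-up of the desynchronization.
#' @param onset_lag_s reaction lag between the cue and the start of the
#'   attenuation (s): subjects begin imagery about half a second after
#'   identifying the cue.
#' @param offset_lag_s persistence of the attenuation past the nominal
#'   task offset (s): imagery stops, and the rhythm recovers, about one
#'   second after the end-of-task beep, so the engaged span of an 8 s
#'   task runs from roughly 1 to 9 s post-cue.
#' @param background_rms per-channel pink-noise RMS (microvolts).
#' @param line_amp amplitude of the common 60 Hz component (microvolts).
#' @return object of class \code{erd_params}.
#' @export
erd_params <- function(
    oscillators = list(
      mu_mid = list(channels = c(Cz = 1, C1 = 0.8, C2 = 0.8,
                                 FC1 = 0.4, FC2 = 0.4),
                    band = c(10, 15), rms = 12),
      mu_lat = list(channels = c(C3 = 1, C4 = 1, CP3 = 0.8, CP4 = 0.8,
                                 CP1 = 0.6, CP2 = 0.6, Pz = 0.4),
                    band = c(10, 15), rms = 10),
      beta_cp = list(channels = c(CP1 = 1, CP2 = 1, Pz = 0.8, CP3 = 0.6,
                                  CP4 = 0.6, P1 = 0.4, P2 = 0.4),
                     band = c(21, 25), rms = 6)),
    depths = list(
      GAIT_MI = c(mu_mid = 0.6, mu_lat = 0.25),
      SIT_MI  = c(mu_mid = 0.25, mu_lat = 0.6, beta_cp = 0.6),
      NOTHING = c()),
    onset_ramp_s = 0.5,
    onset_lag_s = 0.5,
    offset_lag_s = 1,
    background_rms = 10,
    line_amp = 5) {
  for (o in oscillators) {
    if (any(o$channels < 0)) stop("oscillator channel weights must be >= 0")
    if (o$band[1] < 7 || o$band[2] > 34 || o$band[1] >= o$band[2])
      stop("oscillator bands must lie inside 7-34 Hz")
  }
  for (d in depths)
    if (length(d) && (any(d < 0) || any(d > 1)))
      stop("ERD depth must lie in [0, 1]")
  structure(list(oscillators = oscillators, depths = depths,
                 onset_ramp_s = onset_ramp_s, onset_lag_s = onset_lag_s,
                 offset_lag_s = offset_lag_s,
                 background_rms = background_rms, line_amp = line_amp),
            class = "erd_params")
}

#' Eye-blink artifact parameters
#'
#' @param duration_s blink pulse template length (s), biphasic
#'   difference-of-Gaussians shape.
#' @param amplitude peak amplitude at FP1/FP2 (microvolts); must exceed the
#'   background RMS to be a plausible artifact.
#' @param falloff scaling in [0, 1] of the spatial spread beyond FP1/FP2
#'   (0 = blink confined to the prefrontal pair).
#' @param gap_s inter-blink interval inside a deliberate triple blink (s);
#'   the whole triple must fit the 1.6 s detection window.
#' @return object of class \code{blink_params}.
#' @export
blink_params <- function(duration_s = 0.3, amplitude = 80,
                         falloff = 0.5, gap_s = 0.35) {
  if (2 * gap_s + duration_s > 1.6)
    stop("triple-blink span ", 2 * gap_s + duration_s,
         " s exceeds the 1.6 s detection window")
  if (amplitude <= 0 || duration_s <= 0 || falloff < 0)
    stop("invalid blink parameters")
  structure(list(duration_s = duration_s, amplitude = amplitude,
                 falloff = falloff, gap_s = gap_s),
            class = "blink_params")
}

.intent_labels <- c("GAIT_MI", "SIT_MI", "NOTHING", "TEB",
                    "SINGLE_BLINK", "DOUBLE_BLINK")

#' Ground-truth intent timeline
#'
#' @param start_s,end_s,label parallel vectors of interval bounds (s) and
#'   labels from GAIT_MI, SIT_MI, NOTHING, TEB, SINGLE_BLINK, DOUBLE_BLINK.
#' @return data frame of class \code{intent_timeline}, ordered by start.
#' @export
intent_timeline <- function(start_s = numeric(0), end_s = numeric(0),
                            label = character(0)) {
  tl <- data.frame(start_s = start_s, end_s = end_s,
                   label = as.character(label), stringsAsFactors = FALSE)
  if (any(tl$start_s >= tl$end_s)) stop("intervals must have start < end")
  if (!all(tl$label %in% .intent_labels))
    stop("unknown intent label(s): ",
         paste(setdiff(tl$label, .intent_labels), collapse = ", "))
  tl <- tl[order(tl$start_s), , drop = FALSE]
  ## overlap check within each label family (MI-ish vs blink-ish)
  fam <- ifelse(tl$label %in% c("GAIT_MI", "SIT_MI", "NOTHING"), "mi", "blink")
  for (f in unique(fam)) {
    sub <- tl[fam == f, ]
    if (nrow(sub) > 1 && any(sub$start_s[-1] < sub$end_s[-nrow(sub)]))
      stop("overlapping ", f, " intervals in timeline")
  }
  class(tl) <- c("intent_timeline", class(tl))
  tl
}

## background noise matrix: pink per channel + common 60 Hz
.background <- function(montage, n, erd) {
  fs <- montage$sampling_rate
  nch <- length(montage$channel_names)
  dat <- matrix(0, nch, n)
  for (c in seq_len(nch))
    dat[c, ] <- pink_noise(n, fs, rms = erd$background_rms)
  t <- seq_len(n) / fs
  line <- erd$line_amp * sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
  dat + matrix(line, nch, n, byrow = TRUE)
}

## attenuation gain track for one oscillator: 1 at rest, 1-depth inside MI
## intervals of the timeline, with linear ramps at interval edges
.gain_track <- function(n, fs, timeline, erd, osc_name) {
  g <- rep(1, n)
  ramp <- max(1L, round(erd$onset_ramp_s * fs))
  mi <- timeline[timeline$label %in% c("GAIT_MI", "SIT_MI", "NOTHING"), ,
                 drop = FALSE]
  for (i in seq_len(nrow(mi))) {
    d <- erd$depths[[mi$label[i]]]
    d <- if (osc_name %in% names(d)) unname(d[osc_name]) else 0
    if (d == 0) next
    i0 <- round((mi$start_s[i] + erd$onset_lag_s) * fs) + 1
    i1 <- min(n, round((mi$end_s[i] + erd$offset_lag_s) * fs))
    if (i1 <= i0) next
    seg <- i0:i1
    prof <- rep(d, length(seg))
    r <- min(ramp, length(seg))
    prof[1:r] <- d * seq(0, 1, length.out = r)
    prof[(length(seg) - r + 1):length(seg)] <-
      pmin(prof[(length(seg) - r + 1):length(seg)],
           d * seq(1, 0, length.out = r))
    g[seg] <- pmin(g[seg], 1 - prof)
  }
  g
}

## add the ERD-modulated rhythms onto a data matrix
.add_oscillators <- function(dat, montage, erd, timeline) {
  fs <- montage$sampling_rate
  n <- ncol(dat)
  for (nm in names(erd$oscillators)) {
    o <- erd$oscillators[[nm]]
    src <- narrowband_noise(n, fs, o$band, rms = o$rms)
    g <- .gain_track(n, fs, timeline, erd, nm)
    mod <- src * g
    idx <- montage_index(montage, names(o$channels))
    for (j in seq_along(idx))
      dat[idx[j], ] <- dat[idx[j], ] + o$channels[[j]] * mod
  }
  dat
}

#' Generate a seeded motor-imagery training session
#'
#' Produces a continuous recording with \code{n_per_class} trials per task
#' in random order.  Each trial is a 3-5 s pre-cue fixation (uniform),
#' then the task interval: Gait MI and Sit MI last 8 s, Do-nothing 4 s,
#' followed by a short inter-trial gap.  Identical seeds give bit-identical
#' output.
#'
#' @param montage a \code{montage_spec}; @param erd an \code{erd_params};
#' @param n_per_class trials per task (>= 1); @param seed integer seed;
#' @param gap_s inter-trial gap after task offset (s).
#' @return list with \code{recording} (\code{eeg_recording}, events =
#'   trial intervals) and \code{trials} (data frame: trial, cue_s,
#'   cue_sample, duration_s, label).
#' @export
generate_training_session <- function(montage = default_montage(),
                                      erd = erd_params(),
                                      n_per_class = 30, seed = 7,
                                      gap_s = 2) {
  stopifnot(inherits(montage, "montage_spec"), inherits(erd, "erd_params"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  fs <- montage$sampling_rate
  with_seed(seed, {
    labels <- sample(rep(c("GAIT_MI", "SIT_MI", "NOTHING"), n_per_class))
    fix <- stats::runif(length(labels), 3, 5)
    dur <- ifelse(labels == "NOTHING", 4, 8)
    cue <- cumsum(fix + c(0, head(dur + gap_s, -1)))
    total <- cue[length(cue)] + dur[length(dur)] + gap_s
    n <- ceiling(total * fs / fs) * fs   # whole seconds, EDF friendly
    tl <- intent_timeline(cue, cue + dur, labels)
    dat <- .background(montage, n, erd)
    dat <- .add_oscillators(dat, montage, erd, tl)
    trials <- data.frame(trial = seq_along(labels), cue_s = cue,
                         cue_sample = round(cue * fs) + 1,
                         duration_s = dur, label = labels,
                         stringsAsFactors = FALSE)
    events <- data.frame(onset_s = cue, duration_s = dur, label = labels,
                         stringsAsFactors = FALSE)
    list(recording = eeg_recording(dat, montage$channel_names, fs, events),
         trials = trials)
  })
}

#' Biphasic eye-blink pulse template
#' @param blinks a \code{blink_params}; @param fs sampling rate Hz.
#' @return numeric vector (one pulse, peak = \code{amplitude}).
#' @export
blink_template <- function(blinks, fs) {
  n <- round(blinks$duration_s * fs)
  t <- seq(0, blinks$duration_s, length.out = n)
  c1 <- 0.40 * blinks$duration_s; s1 <- blinks$duration_s / 7
  c2 <- 0.72 * blinks$duration_s; s2 <- blinks$duration_s / 5
  p <- exp(-(t - c1)^2 / (2 * s1^2)) - 0.45 * exp(-(t - c2)^2 / (2 * s2^2))
  p * blinks$amplitude / max(abs(p))
}

## per-channel spatial gain of the blink artifact
.blink_gains <- function(montage, blinks) {
  d <- sqrt((montage$coords$x - 0)^2 + (montage$coords$y - 0.95)^2)
  ref <- 0.32                       # ~distance of FP1/FP2 to the mid-brow
  g <- blinks$falloff * exp(-3 * pmax(0, d - ref))
  g[montage$channel_names %in% c("FP1", "FP2")] <- 1
  g
}

#' Inject eye-blink pulses into a recording
#'
#' Adds the biphasic blink template at the given onset times, maximal at
#' FP1/FP2 and attenuated over the scalp according to the falloff factor.
#' Overlapping pulses sum; samples outside pulse supports are untouched.
#'
#' @param rec an \code{eeg_recording}; @param onsets_s pulse onset times (s);
#' @param blinks a \code{blink_params};
#' @param montage montage giving scalp coordinates (defaults to the built-in
#'   10-20 positions for the recording's channels).
#' @return a new \code{eeg_recording} with the artifacts added.
#' @export
inject_blinks <- function(rec, onsets_s, blinks = blink_params(),
                          montage = NULL) {
  if (is.null(montage))
    montage <- montage_spec(rec$channels, rec$fs)
  tmpl <- blink_template(blinks, rec$fs)
  gains <- .blink_gains(montage, blinks)
  n <- ncol(rec$data)
  for (t0 in onsets_s) {
    i0 <- round(t0 * rec$fs) + 1
    i1 <- i0 + length(tmpl) - 1
    if (i0 < 1 || i1 > n)
      stop("blink at t=", t0, " s falls outside the recording")
    add <- outer(gains, tmpl)
    rec$data[, i0:i1] <- rec$data[, i0:i1] + add
  }
  rec
}

#' Default 10 m gait scenario script
#'
#' Stand-up, gait, pause, resume gait, stop, sit-down: six deliberate
#' triple blinks gating the decoder and five motor-imagery engagements.
#' @return an \code{intent_timeline}.
#' @export
default_gait_scenario <- function() {
  intent_timeline(
    start_s = c(5, 10, 30, 35, 55, 60, 65, 85, 90, 95),
    end_s   = c(6.6, 25, 31.6, 50, 56.6, 61.6, 80, 86.6, 91.6, 110),
    label   = c("TEB", "GAIT_MI", "TEB", "GAIT_MI", "TEB", "TEB",
                "GAIT_MI", "TEB", "TEB", "SIT_MI"))
}

#' Random blink-traffic script
#'
#' Builds an intent timeline of deliberate triple blinks interleaved with
#' ordinary single- and double-blink distractors in random order, with
#' natural inter-event spacing (default 3-6 s, i.e. a spontaneous blink
#' rate of roughly 10-15 events per minute).
#'
#' @param n_teb,n_single,n_double event counts; @param blinks a
#'   \code{blink_params}; @param gap_range inter-event spacing range (s);
#' @param seed integer seed; @param start_s time of the first event.
#' @return an \code{intent_timeline}.
#' @export
random_blink_script <- function(n_teb, n_single, n_double,
                                blinks = blink_params(),
                                gap_range = c(3, 6), seed = 11,
                                start_s = 5) {
  kinds <- c(rep("TEB", n_teb), rep("SINGLE_BLINK", n_single),
             rep("DOUBLE_BLINK", n_double))
  if (!length(kinds)) return(intent_timeline())
  with_seed(seed, {
    kinds <- sample(kinds)
    span <- c(TEB = 2 * blinks$gap_s + blinks$duration_s,
              SINGLE_BLINK = blinks$duration_s,
              DOUBLE_BLINK = blinks$gap_s + blinks$duration_s)
    dur <- pmax(unname(span[kinds]), 1.6 * (kinds == "TEB"))
    gaps <- stats::runif(length(kinds), gap_range[1], gap_range[2])
    starts <- start_s + cumsum(c(0, head(dur + gaps, -1)))
    intent_timeline(starts, starts + dur, kinds)
  })
}

#' Generate a seeded scenario stream
#'
#' Renders an intent timeline into a continuous recording: MI intervals
#' carry the class ERD, TEB intervals carry three deliberate blink pulses,
#' SINGLE_BLINK / DOUBLE_BLINK intervals carry distractor blinks.  The
#' returned timeline is the realized ground truth.
#'
#' @param montage,erd,blinks world parameters; @param script an
#'   \code{intent_timeline}; @param seed integer seed;
#' @param duration_s total stream length (default: last interval end + 5 s).
#' @return list with \code{recording} and \code{timeline}.
#' @export
generate_scenario_stream <- function(montage = default_montage(),
                                     erd = erd_params(),
                                     blinks = blink_params(),
                                     script = default_gait_scenario(),
                                     seed = 11, duration_s = NULL) {
  stopifnot(inherits(montage, "montage_spec"))
  if (!nrow(script) && is.null(duration_s))
    stop("empty script needs an explicit duration_s")
  if (is.null(duration_s)) duration_s <- max(script$end_s) + 5
  if (nrow(script) && max(script$end_s) > duration_s)
    stop("script extends past the stream duration")
  span3 <- 2 * blinks$gap_s + blinks$duration_s
  teb <- script[script$label == "TEB", , drop = FALSE]
  if (nrow(teb) && any(teb$end_s - teb$start_s < span3))
    stop("TEB interval shorter than the triple-blink span (", span3, " s)")
  fs <- montage$sampling_rate
  n <- ceiling(duration_s) * fs
  with_seed(seed, {
    dat <- .background(montage, n, erd)
    dat <- .add_oscillators(dat, montage, erd, script)
    rec <- eeg_recording(dat, montage$channel_names, fs,
                         data.frame(onset_s = script$start_s,
                                    duration_s = script$end_s - script$start_s,
                                    label = script$label,
                                    stringsAsFactors = FALSE))
    onsets <- c()
    for (i in seq_len(nrow(script))) {
      k <- switch(script$label[i], TEB = 3, DOUBLE_BLINK = 2,
                  SINGLE_BLINK = 1, 0)
      if (k > 0)
        onsets <- c(onsets, script$start_s[i] + (0:(k - 1)) * blinks$gap_s)
    }
    if (length(onsets)) rec <- inject_blinks(rec, onsets, blinks, montage)
    list(recording = rec, timeline = script)
  })
}
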