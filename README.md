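# gaitBCI

An asynchronous, hybrid motor-imagery brain-computer interface (BCI)
controller for a lower-limb exoskeleton, implemented as a tested R
package.  It is aimed at BCI researchers and engineers who want a
hardware-free, reproducible implementation of the classic
FBCSP decoding stack together with the safety machinery that turns a
noisy 2 Hz command stream into deliberate stand-up / gait / sit-down
actions.

## What it implements

* **EEG decoding** — filter-bank common spatial patterns (FBCSP):
  six zero-phase Butterworth sub-bands (7–9, 10–12, 13–15, 16–20, 21–25,
  26–34 Hz), per-band CSP projections `Z = W E` keeping the first and
  last two components, and within-band log-normalized power features
  `f_j = log(p_j / Σp)` (6 × 4 = 24 features per 2 s window).  Features
  are ranked by mutual information with the label (MIBIF), the top
  *k* (4–10) are kept with CSP pair completion, and a linear
  maximum-margin classifier produces one hard command every 0.5 s
  (first command at *t* = 2.0 s; streaming output is bit-identical to
  offline windowed classification).  Two binary decoders are used:
  Gait-MI vs Do-nothing and Gait-MI vs Sit-MI.
* **Triple eye-blink (TEB) brain switch** — FP1/FP2 average → 2–15 Hz
  zero-phase IIR → undecimated bior1.5 wavelet detail reconstruction →
  Hilbert envelope; a 1.6 s window sliding by 0.4 s fires on exactly
  three supra-threshold peaks, with a robust median + 4·MAD calibrated
  threshold.
* **Finite-state controller** — SIT / Decode-GvN / STAND / Decode-GvS /
  GAIT with three size-10 command buffers, fill/empty ratio 1:3
  (+1 on a correct command, −3 on the opposing one): ten net correct
  commands actuate a transition, and one false detection never can.
* **Evaluation** — bootstrap offline accuracy (100 repetitions, 7:3
  train-test with 10 stratified test trials), TPR/FPR/ACC confusion
  rates, Wolpaw bit rate `Id = log2 N + p log2 p + (1−p) log2((1−p)/(N−1))`
  and ITR `= fd · Id` (bits/min), Fisher-ratio topographies and
  Morlet-wavelet ERSP maps, scenario completion timing.
* **Synthetic EEG** — a seeded generator producing 31-channel, 500 Hz
  sessions and scenario streams: pink background noise, 60 Hz line
  component, band-limited sensorimotor rhythms with class-specific ERD
  signatures, and stereotyped eye-blink artifacts (singles, doubles and
  deliberate triples).  All downstream stages are tested end to end on
  this world; see the methods vignette for what that does and does not
  establish.
* **I/O and CLI** — EDF signal files, CSV event/command/trace tables,
  JSON models and metrics, YAML run configuration, and a `bci_cli()`
  entry point with subcommands (`simulate-session`, `train`,
  `evaluate-offline`, `detect-teb`, `decode-stream`, `run-controller`,
  `run-scenario`, …).

## Worked example

```r
library(gaitBCI)

# a seeded 90-trial training session (30 per task) on the default world
ses <- generate_training_session(n_per_class = 30, seed = 7)
ses$recording
#> <eeg_recording> 31 ch x 575500 samples @ 500 Hz (1151 s), 90 events

# train the Gait-MI vs Do-nothing decoder
m <- train_decoder(ses$recording, ses$trials, "gvn", k = 6)
m
#> <decoder_model> GAIT_MI vs NOTHING, k=6, window 1000/shift 250 samples,
#>   training accuracy 99.8%

# the offline evaluation protocol: 100 bootstrap repetitions
acc <- bootstrap_offline_accuracy(ses$recording, ses$trials, "gvn",
                                  reps = 100, seed = 1)
round(c(mean = acc$mean, sd = acc$sd), 1)
#>  mean    sd
#>  91.4   8.8
```

The bootstrap mean is the per-session analogue of the study-level
"more than 80% offline accuracy" headline; the matching Gait-vs-Sit
decoder reaches 100% on this synthetic world, so the pipeline's
lower bound here is 91.4%.  An accuracy of 0.914 with three tasks and
the printed offline decision rate of 4.60 trials/min corresponds to

```r
itr(0.914, N = 3, fd = 4.60)
#> [1] 4.95          # bits/min
```

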