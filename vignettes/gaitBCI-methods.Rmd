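---
title: "Decoding gait intention from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gait intention from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A lower-limb exoskeleton user who cannot operate a hand controller needs a
hands-free way to issue a small set of high-stakes commands: stand up,
start walking, stop, sit down.  `gaitBCI` implements an asynchronous
hybrid brain-computer interface for exactly this setting:

* a **motor-imagery (MI) decoder** reads event-related desynchronization
  (ERD) of sensorimotor rhythms from 31-channel EEG (10-20 montage,
  500 Hz) and distinguishes *Gait MI vs Do-nothing* and *Gait MI vs Sit
  MI* with two binary classifiers;
* a **triple eye-blink (TEB) brain switch** detected from the prefrontal
  channels FP1/FP2 toggles the decoder on and off, so spontaneous brain
  activity cannot actuate the robot while it is walking or parked;
* a **finite-state machine** with three size-10 command buffers turns the
  0.5 s command stream into safe, deliberate state transitions.

Because the package must be testable without an EEG amplifier or a robot,
it ships a first-class synthetic EEG generator whose output exercises
every stage end to end.

# The decoding pipeline

## Filter-bank common spatial patterns

Each 2 s analysis window (31 x 1000 samples) is zero-phase filtered into
six sub-bands: 7-9, 10-12, 13-15, 16-20, 21-25 and 26-34 Hz
(4th-order Butterworth, applied forward-backward).  Within each band a
common spatial pattern (CSP) projection `Z = W E` is fit from training
data: `W` simultaneously diagonalizes the two class-average normalized
spatial covariances, and the first and last two rows of `Z` — the
variance-ratio extremes — are kept.  Component powers are
log-normalized within the band,

    f_j = log( p_j / (p_1 + p_2 + p_3 + p_4) ),

giving 6 bands x 4 components = 24 features per window.  `exp(f)` sums
to one within each band, and the features are invariant to any global
scaling of the signal.

Design notes:

* **Covariance estimator.** Per-window covariance `E E' / trace(E E')`,
  averaged per class, with shrinkage `C <- (1-l) C + l (tr C / N) I`,
  `l = 1e-4` by default.  Trace normalization is the textbook choice; we
  verified on synthetic data that the headline accuracies are insensitive
  to `l` over 1e-4..5e-2 at the 30-trials-per-class design size, so the
  conventional small default is kept.
* **"Log-normalized"** is read as the classic within-band ratio feature
  (the filter-bank CSP convention), not z-scored log variance.
* **Row ordering.** Components are ordered by descending class-A
  (Gait MI) variance ratio; ties break by first occurrence.  Class A is
  always the first-named class of the pair.
* **No filter state is carried across windows**: every window is filtered
  independently, so offline training windows see exactly the statistics
  the online decoder sees.  (Internally, windows are batched into one
  matrix per band before filtering — the columns are independent, so this
  is purely a speed optimization and bit-identical to per-window calls.)

## Feature selection (MIBIF)

The 24 features are ranked by estimated mutual information with the class
label and the top `k` are kept (`k` = 4..10, default 6; `choose_k()`
cross-validates the choice).  The MI estimator discretizes each feature
by equal-frequency binning with `min(8, floor(sqrt(n)))` bins and then
evaluates the exact discrete MI sum in bits — deterministic and adequate
at the window counts involved (hundreds), in contrast to
kernel-density estimators which introduce bandwidth choices.  Each
selected CSP component drags in its within-band mirror (component 1 with
4, 2 with 3) by default, the usual CSP pairing convention; the flag is
exposed because original descriptions of the method leave it implicit.

## Classifier and online geometry

A linear maximum-margin classifier (L2-regularized squared-hinge SVM,
`C = 1`, inverse-class-frequency weights) is trained on standardized
selected features.  The squared hinge keeps the objective smooth, so a
quasi-Newton solver from a zero start is deterministic; no probability
calibration is applied because the controller consumes hard labels.
A decision value of exactly zero maps to the *non-Gait* class — when in
doubt, do nothing.

Training windows are sliding 2 s windows with 0.5 s shift cut from the
engaged span of each trial: 1-9 s post-cue for the 8 s MI tasks
(13 windows) and 1-5 s for the 4 s Do-nothing task (5 windows), matching
the latency with which ERD develops and dissolves.  The class imbalance
(13 vs 5 windows per trial) is left in the data and compensated by the
classifier's class weights.  Training on sub-windows rather than whole
trials keeps offline feature statistics identical to the online
decoder's input.

Online, the decoder consumes 31 x 10 sample packets, accumulates a 2 s
ring buffer and emits one command per 250 new samples: the first command
at t = 2.0 s, then every 0.5 s, time-stamped at the window end.
Streaming output is bit-identical to offline classification of the same
windows (a tested invariant).

# The TEB brain switch

Both prefrontal channels are averaged, bandpassed to 2-15 Hz (zero-phase
IIR), and enhanced by an undecimated (a-trous) biorthogonal wavelet
decomposition — `bior1.5`, whose step-like shape matches blink
morphology — keeping the detail scales whose pseudo-frequencies fall in
2-8 Hz at 500 Hz (levels 6 and 7).  Reconstruction uses the
time-reversed filter cascade, so the net response is zero-phase.  The
detector then takes the analytic-signal (Hilbert) amplitude envelope,
lightly smoothed (50 ms).  A plain rectified envelope retains the
intra-cycle oscillation of the band-limited blink transient and shows
several local maxima per physical blink; the Hilbert magnitude shows
one hump per blink, which is what a peak counter needs.

Detection slides a 1.6 s window by 0.4 s and fires when **exactly three**
supra-threshold peaks are present; a 2 s refractory period collapses the
multiple windows that cover one physical triple blink into a single
event.  Peak counting uses two guards beyond the absolute threshold:

* **neighborhood dominance** — a local maximum is suppressed if any
  stronger local maximum lies within the 150 ms minimum gap (this is not
  the greedy strongest-first pruning: a suppressed peak still suppresses
  its own weaker satellites, which removes filter-ringing sidelobes at
  200-350 ms from a blink);
* **relative prominence** — a counted peak must reach 40% of the
  strongest peak in its window, because ringing satellites scale with
  blink amplitude and can clear any fixed threshold.  The floor sits
  midway between the satellite level (about 12–15% of the main peak,
  plus envelope noise) and the weakest genuine blink main inside a
  triple (about 80% of the strongest), so both margins are wide.

The threshold itself is calibrated on a blink-free baseline of at least
30 s as `median + 4 * MAD` (scaled MAD) of the envelope — robust to the
heavy tail the blinks themselves would induce, and scale-equivariant, so
amplifier gain changes do not require retuning the multiplier.

# The controller

Five states — SIT, Decode-GvN, STAND, Decode-GvS, GAIT — with the TEB
switch gating entry into the two decoder states, a TEB stopping gait,
and three command buffers of capacity 10:

* Decode-GvN: a GAIT command fills Sit-to-Stand (+1), a NOTHING command
  empties it (-3); a full buffer stands the robot up.
* Decode-GvS: GAIT fills Stand-to-Gait and simultaneously empties
  Stand-to-Sit; SIT does the reverse; whichever buffer fills first fires
  its action.
* Buffers clamp to [0, 10], reset on every state entry, and commands
  arriving outside decoder states are ignored.

The 1:3 fill/empty ratio is read as +1/-3 — a false positive must be
outweighed by three correct commands, which is the safety-conservative
direction; the inverse reading (+3/-1) is available by configuration, as
are the two transition-topology ambiguities (whether gait stop is
TEB- or decoder-triggered, and whether buffers persist across decoder
toggles), since the published state diagram cannot be fully recovered
from text alone.  The system starts in SIT and can only terminate there.

With a decoder that is right 85% of the time, the +1/-3 dynamics form a
random walk with positive drift toward the transition, so scenarios
complete without deadlock (a tested property); a single false GAIT
command can never actuate from a buffer level below 9.

# The synthetic world

The generator states one concrete world and keeps it fixed:

* **Background**: per-channel pink (1/f) noise, RMS 10 uV, plus a
  common-mode 60 Hz line component of 5 uV — so the bandpass stages have
  something real to remove.
* **Rhythms**: three band-limited Gaussian-noise oscillators —
  a midline mu source (Cz/C1/C2/FC1/FC2, 10-15 Hz, 12 uV RMS), a lateral
  centro-parietal mu source (C3/C4/CP3/CP4/CP1/CP2/Pz, 10-15 Hz, 10 uV)
  and a centro-parietal beta source (21-25 Hz, 6 uV).
* **ERD**: multiplicative amplitude attenuation of those sources during
  MI.  Gait MI attenuates the midline mu source by 0.6 and the lateral
  source by 0.25; Sit MI attenuates the lateral mu and the beta source
  by 0.6 and the midline by 0.25.  The spatial/spectral asymmetry is what
  makes Gait-vs-Sit separable, mirroring the reported 10-15 Hz ERD with
  an additional 21-25 Hz component in some subjects.
* **Engagement timing**: attenuation starts 0.5 s after the cue (reaction
  lag), ramps over 0.5 s, and persists 1 s past the nominal task offset —
  so the engaged span of an 8 s task is about 1-9 s post-cue, the same
  span the decoder epochs.  Without the offset persistence, the last two
  training windows of every MI trial would be mislabeled rest, which
  measurably depresses Gait-vs-Nothing accuracy.
* **Blinks**: biphasic difference-of-Gaussians pulses, 0.3 s, 80 uV at
  FP1/FP2, spatial falloff scaled by a factor in [0, 1] (0 confines them
  to the prefrontal pair); deliberate triples use a 0.35 s inter-blink
  gap so the triple spans about 1 s, inside the 1.6 s detection window;
  distractor singles/doubles arrive every 3-6 s, a natural spontaneous
  blink rate.
* **Sessions**: 30 trials per task in random order; 3-5 s uniform
  pre-cue fixation; 8 s MI and 4 s Do-nothing tasks; 2 s inter-trial gap.

ERD depth and signal-to-noise are *free parameters of the world*, not
claims about any subject population: the study this design follows does
not report them.  The defaults above were chosen once as a plausible
"clear ERD" regime and are exposed in `erd_params()`.

What a green test does establish: the pipeline recovers the class
structure it is supposed to recover, at the stated sizes, with the
stated protocols, including its failure behavior under permuted labels.
What it does not establish: human-subject performance.  The synthetic
world has no volume conduction, no EMG or movement artifacts, no
non-stationarity across a session, and its rhythms are Gaussian —
real EEG is harsher in all four respects.

# Numerical choices and degenerate inputs

* Butterworth design follows the analog-prototype + bilinear route and
  matches `scipy.signal.butter` coefficients to full precision; gain is
  normalized exactly at the prewarped band centre.
* Filtering runs as a cascade of second-order sections (one conjugate
  pole pair per biquad, zeros split between z = 1 and z = −1), not the
  expanded order-8 polynomial recursion: for the narrow 7–9 Hz band at
  500 Hz the expanded form is so ill-conditioned that rounding noise is
  amplified to ~1e−4 relative error, which breaks the scale-invariance
  of the CSP features.  The cascade is implemented in C++ (the package's
  only compiled code), as each bootstrap repetition filters hundreds of
  windows into six bands.  Windows are additionally divided by their
  global RMS before filtering — a mathematical no-op for the
  scale-invariant features that makes the invariance hold numerically
  (to ~1e−10).
* Forward-backward filtering uses odd-reflection padding of three filter
  lengths; inputs shorter than the padding are rejected rather than
  silently filtered.
* Rank-deficient composite covariances are clamped with a warning;
  zero-variance CSP components are floored at machine epsilon with a
  warning rather than producing `-Inf` features.
* MI estimates are clipped at 0; a constant feature has MI exactly 0;
  ranking ties break toward the lower feature index everywhere.
* `bit_rate()` handles the `p = 1` limit as `0 log 0 = 0` and flags
  below-chance accuracies instead of failing.
* EDF output quantizes to 16 bits with symmetric per-channel ranges and
  pads the final one-second record with zeros; round trips are exact to
  half a quantization step.
* Scaled-down protocol sizes in the regular test-suite (smaller sessions,
  fewer repetitions) are used where the full-scale run lives in the
  acceptance criteria; the acceptance tests run the stated 100-repetition
  bootstraps, the 97-triple-blink stream and the 40.5 min blink-only
  stream at full size.

# Known limitations

* The per-subject information-transfer rates of the original study
  cannot be recomputed without per-subject decision rates, which are not
  printed; `itr()` therefore accepts the decision rate as an input with
  the printed averages (4.60 offline, 5.97 online trials/min) as
  defaults.
* The exact CSP variant, the MI estimator for continuous features, the
  wavelet order, the peak threshold rule and the FP1/FP2 combination rule
  are all unstated in the source material; each is implemented with the
  field-standard choice and exposed in configuration.
* No adaptive or online CSP updating, no channel selection, no
  deep-learning decoders: all explicitly future work in the source
  design, and out of scope here.
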