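---
title: "Decoding finger kinematics from sEMG grids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger kinematics from sEMG grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `semgdecode`: what each stage
models, which parameters matter and why their defaults were chosen, what
the synthetic sessions do and do not emulate, and where the design was
genuinely open.

## The decoding problem

Surface EMG recorded from a 4×4 dry-electrode grid over the extensor
digitorum carries enough information to estimate hand pose. The package's
pipeline learns a regression from 512 ms sEMG windows to the 16 joint
angles tracked by an optical hand tracker, then classifies gestures from
the predicted angle vectors. The stages: session simulation (or loading),
filtering and normalization, kinematic smoothing and resampling,
median-deviation outlier rejection, rolling-window grid tensorization,
transformer regression, extra-trees classification, and an evaluation
battery.

## The synthetic session generator

Real multi-channel recordings with synchronized hand tracking are not
redistributable, so `make_session()` generates sessions that follow the
acquisition protocol and the statistical structure the decoder relies on.

**Protocol.** 14 gestures × 7 repetitions = 98 events in seeded random
order; 5 s holds, 3 s pauses, a leading pause before the first cue;
repetition indices count chronological occurrences per gesture. Optional
`cue_jitter_sd` shifts onsets slightly *earlier* (subjects tend to
anticipate the auditory cue), keeping events non-overlapping.

**Kinematics.** Piecewise trajectories: rest pose (the midpoint of each
joint's range, 45° for flexion joints, 0° for abduction joints) during
pauses, a linear 0.5 s ramp into the gesture's template pose, a plateau
during the hold, and a ramp back. I.i.d. Gaussian estimator noise
(default SD 2°) emulates optical-tracker jitter.

**sEMG.** Per channel: an activation envelope times a band-limited
(20–450 Hz) Gaussian carrier — the standard surrogate for
interference-pattern EMG — plus 50/100 Hz line interference (10/5 µV),
white baseline noise (3 µV), and rare brief all-channel spikes
(2/min, 200 µV, 5 ms) emulating mechanical artifacts. The envelope
follows the active gesture's per-electrode gain, rises 100 ms *after*
the kinematic onset (electromechanical delay; sEMG onset follows motion
onset), and is scaled per repetition by a lognormal force factor with
mean 1 and CV 0.15, reflecting that subjects receive no force feedback.
Within each hold the envelope additionally wanders under a slow
lognormal force drift (SD 0.12 on the log scale, 1 s timescale, common
to all channels): EMG amplitude varies even while the pose is static,
and a simulator with constant within-hold envelopes would let a decoder
key on carrier identity instead of amplitude. These noise levels were
fixed once as a realistic "moderate noise" condition and are the
condition under which the acceptance experiments run.

**Templates.** The 14 shipped gestures are finger-involvement codes
(which fingers flex, extend, spread). Angles: rest ± 40° on the involved
fingers' flexion joints, ±15° on abduction joints for spread/squeeze
postures. Envelope gains localize each finger on the grid with compact
Gaussian profiles; extension and flexion of the same finger load
*spatially distinct* regions (extensor compartments vs flexor crosstalk
as seen from an extensor-site grid), and spread/squeeze add an
interosseous-like row-2 contrast. This matters: with purely
magnitude-coded flexion/extension, a fist and an open palm would differ
only by a scale factor, which per-repetition force variability makes
unreliable — electromyographically "well-separated" templates must differ
in activation *direction*. The minimum pairwise normalized-gain distance
of the shipped set is ≈ 0.27 (asserted in the tests). Template
similarity is deliberately a free difficulty knob (`separation`, or
user-supplied matrices).

**What the simulator does not model:** motor-unit physiology, volume
conduction, electrode-skin impedance drift, realistic crosstalk anatomy,
tracker occlusions (beyond i.i.d. noise), non-stationary fatigue
spectra. Passing tests on synthetic cohorts therefore demonstrates that
the *pipeline machinery* is correct and that the decoder can recover a
known mapping at realistic SNR — not that any given accuracy will be
attained on real muscle.

## Preprocessing

* **Line noise**: notch biquads (standard constrained two-pole design,
  Q = 30 — the notch quality is not dictated by the method, so it is a
  parameter) at 50 and 100 Hz. Only the listed frequencies are notched by
  default; `comb_harmonics = TRUE` extends each to all harmonics below
  Nyquist. Keeping 150 Hz intact preserves in-band sEMG content.
* **High-pass**: 4th-order Butterworth, 20 Hz cutoff, removing motion
  artifact and baseline drift.
* **Zero-phase application**: all IIR stages run forward–backward by
  default. Offline decoding gains nothing from causal filtering, and
  envelope timing (the 100 ms electromechanical lag) would otherwise be
  distorted; the magnitude response is squared, so the designed high-pass
  reaches −6.02 dB at its cutoff. A causal mode remains available.
* **Normalization**: per-channel z-score over the whole recording.
  Computing statistics per recording (rather than per split) mirrors
  offline practice; a constant channel yields zeros with a warning.
* **Kinematic smoothing**: order-1 Savitzky–Golay (a weighted moving
  average) with a 502-sample window, adjusted to 501 (the symmetric
  formulation needs odd lengths). The package's default pipeline
  *resamples the kinematics to the sEMG clock first and smooths second*:
  501 samples at 4000 Hz spans 125 ms, which suppresses estimator jitter
  while leaving 5 s holds untouched, whereas the same window at the
  tracker's native 120 Hz would span 4.2 s — longer than a hold minus its
  transitions — and would smear entire events into their surrounding
  pauses, biasing every plateau target. Both orders are available since
  smoothing and resampling are separate functions.
* **Outlier rejection**: within each annotated gesture interval, the
  per-joint median is computed and samples whose maximum joint deviation
  reaches 15° are dropped. On synthetic sessions this predominantly
  removes transition-ramp samples (≈ 6% of interval samples under the
  default 0.5 s transitions), which is exactly its intent: mistakes and
  corrections look like large transient deviations. Windows overlapping
  any rejected sample are excluded from training and evaluation.

## Windowing and augmentation

Rolling windows of 512 ms with stride t give L = ⌊(N−S)/t⌋ + 1 windows;
partial trailing windows are discarded to keep tensors rectangular.
Channels are placed on the 4×4 grid according to the session's layout
map (hardware metadata; row-major by default). Per-window targets are
the smoothed angles at the *window end* by default — the causal choice:
predict the current pose from the immediately preceding signal — with
window-center and window-mean policies available for ablation. Windows
whose target time falls inside an annotated event carry its gesture
label, otherwise `rest`.

Training-time augmentation follows the channel-silencing scheme: each
channel of each window is silenced with probability 0.5 for one span of
duration uniform on 6–400 ms (onset uniform among positions where the
span fits; longer spans are truncated with a warning), then i.i.d.
Gaussian noise of SD 0.1 is added to the z-scored signal. One span per
selected channel, matching the singular "a duration" of the scheme's
description. Every draw is seeded and logged.

## The decoder

A factorized self-attention transformer for video-shaped tensors,
ordered as: patch embedding → spatial-attention encoder blocks (over the
16 grid cells within each temporal token) → temporal-attention blocks
(over the patch sequence within each cell) → per-cell temporal mean
pooling, cells concatenated → linear head to 16 angles. Pre-norm
residual blocks, learned spatial and temporal positional embeddings,
Adam, MSE loss on per-joint standardized degrees (standardization is
metadata on the fit; predictions return in degrees). Early stopping
monitors validation loss and restores the best checkpoint.

Three choices deserve explanation:

* **Nonlinear patch stem.** Interference-pattern sEMG is zero-mean and
  carries its information in within-patch *power*: a purely linear patch
  projection of a zero-mean carrier is information-free in expectation,
  and layer normalization then removes token scale before the encoder
  MLPs could square it. The patch embedding is therefore a small
  two-layer (GELU) map, which turns patch amplitude into token content
  before any normalization. This measurably changes parameter recovery
  on synthetic sessions from ceiling-limited to near the noise floor.
* **Cell-preserving pooling.** The final fully connected layer reads the
  *per-cell* temporal means, concatenated over the 16 grid cells, rather
  than one globally pooled token. Global pooling averages cell-specific
  amplitude into shared feature dimensions, so reading "the amplitude of
  one electrode" back out requires the encoder to learn position-gated
  features — a representation small models trained at desk scale
  reliably bypass by memorizing. Gestures that differ in a single
  muscle compartment (e.g. thumb state) are decodable only if cell
  identity survives pooling; preserving it structurally cut held-out
  regression error by a factor of five in the package's synthetic
  benchmark.
* **Small defaults.** The reference architecture's capacity is not
  dictated by the method, so defaults (embedding 64, depths 2+2, heads
  4; the end-to-end experiment uses an even smaller 32/1+1 variant with
  256-sample patches) are sized so a subject trains in minutes on one
  CPU core. Everything is configurable; the implementation is plain
  matrix algebra with hand-written backpropagation, verified against
  numerical gradients in the test suite.

Training details: global gradient-norm clipping at 1 (a numerical
safeguard), optional step learning-rate decay, batch shuffling,
augmentation applied to training batches only, and full seeding —
identical calls are bit-reproducible.

## Classifier and evaluation

The gesture classifier is an extremely randomized trees ensemble
(100 trees, random split thresholds, no bootstrap — the classical
construction, via `ranger`) on the decoder's 16-D angle output.
Window-level votes are aggregated per gesture event by majority vote
(ties break lexicographically); per-window scores are also available.

Metrics: normalized joint error (|error|/range, with configurable
anatomical ranges defaulting to 90° flexion / 40° abduction arcs — tests
always inject explicit ranges); confusion matrices with accuracy =
trace/total and one-vs-rest F1; Pearson correlation between per-subject
accuracy vectors across settings (defined over per-subject accuracy, and
requiring ≥ 3 subjects); two-sided paired t-tests (zero-variance
differences return a flagged degenerate result instead of ±∞);
inter-onset-interval CDFs against the ideal 8 s cycle; and the classical
EMG features — zero crossings and slope sign changes with a 0.01
dead-band on z-scored units (suppressing numerical chatter; the feature
definitions carry no canonical threshold), and the spectral centroid of
a Hann-tapered periodogram over 20–450 Hz, whose variance across windows
indexes spectral nonstationarity. Feature granularity (window, event,
recording) is the caller's choice via `signal_features()` /
`signal_feature_table()`.

## The end-to-end experiment

`decode_experiment()` chains everything on one simulated subject:
simulate 98 events; filter; resample + smooth kinematics; outlier mask;
segment at 512 ms / 32 ms stride; keep windows that lie wholly inside
the settled plateau of each hold (0.7 s after onset: transition + lag +
margin) and cap them at 25 evenly spaced windows per event; split by
repetition ({2,3,6,7} train / 4 validation / 5 test, repetition 1
dropped); train the compact decoder (30 epochs, step learning-rate
decay, early stopping, Gaussian-noise augmentation only — channel
silencing would destroy the non-redundant single-compartment cues on a
16-channel grid and measurably hurts recovery here, though it remains
the augmentation default for real multi-session use); report
event-level majority-vote accuracy on repetition 5, plateau angle MAE
against the true templates, and a label-shuffled chance control.

Problem sizes were chosen so the whole experiment runs in roughly ten
minutes on a single core: the 32 ms stride (relaxed from 2 ms) and the
20-window cap subsample the training stream without touching the
protocol, hold structure or noise levels. The 2 ms reference stride
remains the windowing default.

## Numerical notes and limitations

* Filters: `signal::butter`/`filtfilt`; notch biquads designed
  in-package (the standard RBJ formula); edge transients are why
  steady-state gains are measured on trimmed interiors in tests.
* Degenerate inputs: constant channels under z-score → zeros + warning;
  empty annotation intervals, too-short tracks and non-divisible token
  geometries produce informative errors rather than silent misbehavior.
* Determinism: every stochastic component draws from seeds derived
  deterministically from one master seed; RNG state of the caller is
  always restored. `ranger` is run single-threaded with a fixed seed.
* The simulator's i.i.d. angle noise and stationary carriers are kinder
  than real data; transfer across sessions/subjects, electrode shift and
  fatigue are out of scope, as are the real-subject accuracy levels —
  those require the original recordings.
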