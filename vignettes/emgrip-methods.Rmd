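---
title: "emgrip: methods, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emgrip: methods, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgrip)
```

## The problem

A myoelectric prosthesis reads surface electromyography (sEMG) from the
residual forearm and maps muscle tasks to actuator motions. `emgrip`
re-implements one such controller as testable R code: three sEMG channels
at 1 kHz (flexor, mid-forearm, extensor placements), three tasks — wrist
flexion (class 1), fist (class 2), wrist extension (class 3) — and a
two-axis gripper (open/close clamp, turning base). This vignette records
the model, the synthetic-data design, the numerical choices, and where
the design was genuinely open, why each decision was made.

## Signal model and preprocessing

**Sampling.** sEMG carries its discriminative information in roughly the
50–150 Hz band, so the Nyquist bound gives a 300 Hz floor
(`nyquist_min_rate(150)`); the pipeline assumes 1 kHz, which leaves room
for short smoothing blocks.

**RMS envelope** (`rms_envelope`). Each channel is cut into consecutive
*non-overlapping* blocks of 50 ms (N = 50 samples at 1 kHz) and each
block is reduced to its root-mean-square `sqrt(sum(x^2)/N)`. The trailing
remainder shorter than one block is dropped, so a window of `W` samples
yields exactly `floor(W/N)` envelope samples. A hop parameter exists for
experimentation but defaults to the block length. 50 ms is the default
because much longer blocks blur the activation course and much shorter
ones keep too much interference noise.

**Peak-dynamic normalization** (`peak_normalize`). Each channel of the
envelope is divided by that channel's maximum *over the whole 2 s
analysis window* (`X / X_peak`), bounding values to [0, 1]. Two open
points were settled as follows:

* *Which "window" supplies the peak?* The full analysis window, not the
  50 ms block: per-block normalization would force every block's maximum
  to 1 and erase the amplitude structure the features rely on. The
  envelope block length stays selectable, so the alternative reading can
  be explored by passing a 2000 ms block.
* *Zero-peak channels* (rest-only windows in a stream) map to all zeros
  rather than raising an error, so the streaming loop can process silence.

No separate high-pass or notch filter stage is applied: envelope
smoothing is the filtering step of this pipeline. A pre-filter can be
applied to the matrix before constructing the window if desired.

## Features

Both feature sets operate on the normalized envelope, per channel,
concatenated channel-major (`extract_features`):

* **Subwindow RMS** (`rms_features`, default): consecutive 500 ms
  subwindows, each reduced to its RMS — four values per channel on a 2 s
  window, 12 features total. This preserves the temporal course of the
  activation, which is what distinguishes a burst from steady noise after
  per-channel normalization.
* **Statistical** (`statistical_features`): MAV, MAV1, MAV2, median
  absolute value, variance, standard deviation — six per channel. The
  weighted variants use the standard literature profiles: MAV1 weights
  the central 25–75 % of samples 1 and the tails 0.5; MAV2 replaces the
  flat tails with continuous ramps, `4n/N` rising into the central band
  and `4(N−n)/N` falling out of it. (Some sources print the falling ramp
  as `4(n−N)/N`, which is negative; the symmetric decreasing ramp is used
  so that MAV2 of a [0, 1] envelope stays in [0, 1].) Variance and SD use
  the population denominator N, consistent with the envelope's 1/N
  convention.

The total feature width fed to the network is never dictated by the
protocol itself; 12 = 3 channels x 4 subwindows is the arithmetic
consequence of the 2 s window and 500 ms subwindow defaults and is the
default input width.

## Classifier

`build_mlp` constructs the five-layer architecture
`dense(h1) → dropout(0.2) → dense(h2) → dropout(0.2) → dense(out)`.
Design points:

* **Hidden widths** are not fixed by the protocol; h1 = 32, h2 = 16 are
  the defaults (configurable), small enough for microcontroller-class
  deployment while fitting the 12-feature input.
* **Hidden activation** is rectified-linear (standard for this family;
  configurable in principle via the layer spec).
* **Output**: softmax + categorical cross-entropy for the multiclass
  model. The two-class flexion/extension variant uses a *single sigmoid
  unit with binary cross-entropy* — mathematically the 2-class case —
  even though the original description pairs the sigmoid with a
  categorical loss; that pairing appears to be a documentation slip and
  is not reproduced.
* **Initialization**: weights uniform in ±1/sqrt(fan_in), biases zero,
  from a mandatory integer seed. Training (Adam, β₁ = 0.9, β₂ = 0.999,
  ε = 1e−8; lr 0.001, 300 epochs, batch 8, stratified 60/20/20 split) is
  reproducible from the config seed, which also drives epoch shuffling
  and the inverted-dropout masks.
* **Ties**: argmax breaks exact probability ties toward the lowest class
  id; a sigmoid output of exactly 0.5 therefore predicts the lower class.
* **Divergence**: a non-finite training loss aborts with a diagnostic
  rather than returning a silently broken model.

`random_search` draws learning rates log-uniformly in [1e−4, 1e−2] and
epochs from {100, 200, 300} (batch size constant), scores each draw on
the validation split, and breaks ties by draw order. Failed trials are
recorded in the trial table, not fatal.

## Evaluation protocol

`kfold_cv` assigns windows to k = 10 stratified folds (per class:
shuffle, deal round-robin, so fold sizes differ by at most one per
class), trains a fresh seeded model per fold on the other folds, and
pools all held-out predictions for the headline metrics; per-fold metrics
are reported alongside, since it is not knowable from the original
description which of the two aggregations produced its tables. `k = n`
degenerates to leave-one-out. Precision and recall are macro-averaged
(per-class one-vs-rest, equal class weight) — the symmetric choice for a
balanced three-class problem; a class never predicted contributes
precision 0. Loss is the mean cross-entropy of the pooled test
predictions. Inside each fold the model trains on all non-test windows
(no inner validation split): the 60/20/20 split is a single-model
training regime, and re-applying it inside folds would discard a third of
each fold's training data.

`window_sweep` re-segments and re-featurizes at each candidate duration —
the subwindow count scales with the duration, e.g. a 0.5 s window yields
one RMS value per channel — and reports CV accuracy per duration.
`compare_feature_methods` reuses a single seeded fold assignment across
methods so the comparison differs only in the features.

## Streaming and actuation

`stream_classify` consumes consecutive **non-overlapping** 2 s windows
(a sliding hop is available but off by default: the controller's reaction
time is one window plus inference, implying no overlap), featurizes with
the RMS method, classifies, and gates at confidence **strictly greater
than 0.70** ("greater than" is read literally). Commands: class 1 →
gripper +20° (clockwise, close), class 2 → base +30°, class 3 → gripper
−20° (open); positive angles are clockwise throughout. The virtual
prosthesis clamps angles to per-axis limits — gripper [0°, 90°], base
[0°, 180°], arbitrary bounds standing in for unspecified servo limits —
and a gated (below-threshold) window leaves the state untouched. The
trailing partial window of a stream is discarded.

## The synthetic generator: what it emulates, and what not

`build_schedule`/`synthesize_recording` emulate the acquisition protocol:
randomized task cues, 5 s contraction + 10 s rest, 10 cues per class
(the documented session length, 7 min, slightly disagrees with
30 × 15 s = 7.5 min; the generator exposes the primitive durations and
does not force a total). Muscle activity is modelled as:

* **Band-limited bursts**: Gaussian noise FFT-masked to 50–150 Hz, unit
  RMS, multiplied by a raised-cosine onset/offset ramp (0.1 s) — the
  simplest process matching the stated informative band and task timing
  without a physiological motor-unit model.
* **Per-task channel gains**: flexion dominant on channel 1, fist on
  channel 2, extension on channel 3, with weak (0.15) mid-channel
  co-activation for the wrist tasks. `class2_overlap` mixes the fist row
  toward the even mixture of the flexion and extension rows — one knob
  that reproduces the observed confusion structure (the amputee subject's
  fist activated nearly the same muscles as the wrist tasks). The default
  0.5 states partial confusability; 0 is the separable configuration, 1
  the fully mixed one.
* **Amplitude jitter**: per-event, per-channel lognormal gain variability
  (sdlog 0.4, i.e. roughly ±50 % trial-to-trial — realistic for repeated
  voluntary contractions). This is what makes overlapped fist events
  genuinely confusable with the wrist classes rather than merely close.
* **Baseline noise** sd 0.05 (signal units are arbitrary
  sensor-amplified units; no mV calibration is attempted) and
  **near-constant IMU columns** (constant offsets + sd 0.01 white noise),
  because the gyroscope carried no task information in the original
  recordings.

What the generator does *not* emulate: motor-unit recruitment and firing
statistics, electrode lift/motion artifacts, inter-session electrode
placement shift, muscle fatigue, power-line interference. A green
recovery test therefore establishes that the pipeline recovers the
structure this generator states — band-limited, gain-patterned bursts
under amplitude jitter — not that it would reach the same numbers on real
recordings; the published real-data metrics (78.67 % multiclass,
95.13 % binary) require the deposited dataset and are deliberately not
asserted anywhere in the test suite.

## Numerical and testing choices

* Determinism is absolute: every stochastic step (schedules, noise,
  splits, folds, init, shuffling, dropout) derives from explicit integer
  seeds via a fixed integer-hash child-seed rule, and the acceptance
  suite asserts bit-identical reruns of the entire pipeline.
* Oracle tests compare every numerical stage (envelope, normalization,
  both feature sets, the forward pass) against explicit-loop brute-force
  reimplementations on 100 randomized instances, at 1e−9 relative
  tolerance (observed agreement is ~1e−15).
* Model JSON serialization round-trips weights through full-precision
  decimal text; agreement is ~1e−15 relative, not bit-exact, which is
  why the round-trip test tolerates 1e−12.
* The streaming-recovery criterion (≥ 80 % correct command polarity on an
  alternating flexion/extension stream) is evaluated *pooled over the
  five test seeds* (100 decision windows total), the natural reading of
  "over 5 seeds" and the statistically stabler estimate; per-seed values
  at the frozen seeds range 0.75–0.95.
* CV-heavy unit tests run at reduced epochs to keep the suite fast; the
  full 300-epoch regime runs in `test-acceptance.R`.

## Known limitations

Single-subject by construction (no inter-subject generalization), no
frequency-domain features (excluded by design for real-time cost), no
sliding-window majority voting, and the MLP is plain R matrix code —
adequate for these sizes (a full 10-fold CV at 300 epochs takes seconds),
not for larger architectures.
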