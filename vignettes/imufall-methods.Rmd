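---
title: "Methods: multi-IMU fall detection with imufall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-IMU fall detection with imufall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`imufall` implements a complete fall-detection pipeline for a body-worn
network of nine 9-DOF inertial measurement units (IMUs) sampled at 15 Hz:
one node on the chest and one on each elbow, wrist, thigh and ankle. The
pipeline has six stages:

1. **Synthetic motion** — a kinematic simulator that generates labeled
   multi-node recordings of six fall types and three fall-like activities;
2. **Global calibration** — every node's local frame is rotated into one
   shared north-east-up (NEU) earth frame using gravity and magnetic
   reference vectors averaged over a 1-second (15-sample) static stance;
3. **Orientation** — a Mahony attitude and heading reference system (AHRS)
   estimates each node's quaternion over time;
4. **Features** — 13 channels per node (calibrated acceleration, angular
   rate, quaternion, Euler angles) are summarized over sliding windows by
   four statistics (mean, range, population standard deviation, mean
   absolute deviation), 52 features per node, 468 for all nine;
5. **Classification** — a stacked LSTM (128/32/16 units) with a dense-8
   ReLU layer and a 2-unit softmax, trained with Adam (learning rate 0.01,
   batch size 10) on sparse categorical cross-entropy;
6. **Evaluation** — sensitivity/specificity/accuracy, ROC/AUC,
   per-activity tables, and a sensor-placement ablation over the 30
   standard combinations of the five placement groups (C, E, W, T, A).

The real firefighter dataset this design targets is private, so the
simulator is a first-class, tested component: every downstream stage is
exercised on data whose ground truth is known exactly.

## The synthetic motion model

The body is modeled as a rigid inverted pendulum pivoting at the ankles,
with articulated limb segments (arms about the shoulders, legs about the
hips) — deliberately far simpler than full biomechanics, but rich enough
to produce class-separable yet overlapping signatures. Each trial is:

* a **2-second quasi-static standing prefix** (the calibration stance; the
  1-second averaging requirement is always satisfied);
* a short **postural sway** (±0.8°) so the boundary between stance and
  movement is non-trivial;
* the **scripted activity**;
* a still tail (lying after falls, standing/seated otherwise).

Activity schedules are piecewise smooth trunk-tilt trajectories θ(t):
falls accelerate quadratically toward 90° tilt in a direction set by the
activity (forward F1/F2/F5, backward F6, left F3, right F4); F1 and F6
include a mitigation plateau (knee or seat contact) before the final
collapse; F5 precedes its fall with a slow crouch. The fall-like
activities produce partial trunk pitch without impact: FL1 is a crouch
(vertical drop, 70° thigh flexion, 20° trunk pitch), FL3 a sit-down, and
FL2 walks with a 40° stoop with periodic thigh/ankle/arm swing — FL2 is
intentionally tuned to share trunk-pitch statistics with the slow fall
F5, so the negative class genuinely stresses the classifier.

Ground-truth node orientations R(t) and positions p(t) are evaluated on a
fine internal grid (≥240 Hz) and the sensors synthesized exactly:

* `accel = R'(t) (p̈ − g) + bias + noise` (specific force; a static node
  reads +9.81 m/s² along its body-frame up axis),
* `gyro = ω_body + bias + noise` with ω from the quaternion increments,
* `mag = R'(t) m_earth + bias + noise`.

The earth field defaults to 30 µT horizontal north plus 40 µT downward
(a mid-latitude dip); gravity is 9.81 m/s². Ground impacts add a decaying
12 Hz oscillation to the world-frame acceleration (25–35 m/s² for direct
falls, less for knee/seat contacts, a small bump when sitting down). Each
trial is rotated by a random heading and each node wears a random
mounting orientation, so calibration genuinely has work to do.

**Labels.** A fall action has three phases — early fall, impact,
recovery — and the positive label covers the early-fall phase only: from
the instant the trunk angular rate first exceeds 20 deg/s (a
generator-internal threshold; the source protocol gives no quantitative
boundary) until the first ground contact. Fall trials therefore carry
exactly one contiguous labeled run; fall-like trials carry none.

**Noise defaults** (all configurable): white noise σ of 0.15 m/s²
(accelerometer), 0.5 deg/s (gyroscope), 0.5 µT (magnetometer), plus
per-axis constant biases drawn once per trial and node (σ 0.05 m/s²,
0.2 deg/s, 0.3 µT). Subject statures are uniform on 1.70–1.88 m (the
study population range) with standard anthropometric segment fractions.
Fall durations (~0.65–1.0 s to impact) and impact magnitudes are
plausible placeholders chosen once — the private dataset they stand in
for cannot calibrate them.

**What the simulator does not emulate**: soft-tissue and garment
artifacts, magnetic disturbance, sensor saturation/dropout, subject
idiosyncrasy beyond stature, and the full kinematic variety of real
falls. Passing tests on this data demonstrate that the pipeline's
machinery is correct and that its discriminative signal flows end to
end; they do not certify real-world detection rates.

## Calibration

With the subject standing still, the first 15 samples of accelerometer
and magnetometer are averaged into reference vectors `V_acc` and
`V_mag`. The NEU rotation is the deterministic TRIAD construction:
U = V_acc/|V_acc| (specific force points up), N the unit horizontal
component of V_mag, E = U × N, and the rotation has rows (N, E, U). The
construction is exact on noise-free inputs and accurate to well under 2°
at the default noise level (the 15-sample averaging gains √15). A prefix
whose mean gyro magnitude exceeds 2 deg/s is rejected — calibration
refuses rather than silently mis-calibrating. All three vector channels
(including the gyroscope) are rotated into NEU; the source description
does not state whether angular rate is rotated, and rotating everything
keeps all downstream channels in one frame.

## Orientation

The Mahony AHRS corrects gyro integration with the cross products
between measured and quaternion-predicted gravity and magnetic field
directions, scaled by a proportional gain (Kp = 1, Ki = 0 by default —
pure proportional feedback is standard at low sample rates; both are
configurable). The filter is initialized from the TRIAD attitude of the
first 15 samples so it starts converged; after calibration that attitude
is the identity. Quaternions are renormalized every step; Euler angles
use the intrinsic Z–Y′–X″ (yaw–pitch–roll) convention with the pitch
argument clamped to [−1, 1] — the convention is fixed here because the
source names the angles but not their order.

## Features and sequences

At 15 Hz the 0.5 s window is 7.5 samples; the package rounds to 8
samples and the 0.1 s hop to 2 (both overridable in samples, so the
7-sample alternative is available). A window is labeled fall if **any**
sample inside it is labeled — the early-fall phase is short, and the
any-rule preserves it; a majority rule is available. Before training,
features are z-scored with statistics fitted on the training split only
(default, toggleable). This choice was forced empirically: the window
statistics span several orders of magnitude across channels (quaternion
components near 1, Euler means and ranges up to 360°, accelerations in
tens of m/s²), and at the specified 0.01 learning rate the wide
468-input LSTM trains unreliably on the raw scales — on the full
synthetic protocol it diverged on some seeds while narrow single-node
models did not, which would have inverted the placement comparison for
reasons that have nothing to do with sensor placement.

Classifier inputs are runs of 10 consecutive windows (~1 s of context at
the 0.1 s hop, echoing the batch-size-as-one-second remark in the source
recipe), labeled by their final window; sequences never span trial
boundaries. The construction is configurable (length, stride).

## Training protocol

The 80/20 split is performed at the **trial** level, stratified by
activity, so no window of a held-out trial ever leaks into training.
Fall windows are a minority (~15% of sequences), so inverse-frequency
class weights are applied by default. All randomness — the split, weight
initialization (Glorot uniform, forget-gate biases at 1), epoch
shuffling, sequence subsampling — derives from the configured seed, and
training is deterministic given it: the C++ core (RcppArmadillo)
consumes pre-drawn permutations and performs no random draws of its own.
Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e−7.

A NaN/Inf batch loss aborts training with the epoch index. The softmax
output, ReLU activation and cross-entropy match their standard
definitions exactly and are pinned by tests (including a
finite-difference check of the full backpropagation).

## Evaluation and the placement ablation

Confusion counts use a 0.5 probability threshold; ROC sweeps the unique
scores with ties crossing together and integrates by trapezoid (the AUC
equals the Mann–Whitney pairwise estimate, which the tests verify
brute-force). In per-activity tables, fall-like activities have no true
falls, so their sensitivity is reported as 0 by convention and their
specificity equals their accuracy.

The ablation trains one model per placement combination on the *same*
trial split and seed, so differences between rows reflect sensor sets,
not resampling. The default list is the 30 standard combinations (of the
31 non-empty subsets of {C, E, W, T, A}, the subset CTA is not part of
the standard list; `ablation_combinations(all = TRUE)` adds it). Whether
the original protocol retrained per combination or masked a single
model is unstated; retraining per combination is the plain reading and
is what this package does.

## Problem sizes for the shipped evaluation protocol

The package's acceptance script and end-to-end tests run on the full
simulated protocol — 14 subjects × 35 trials = 490 recordings, 8 s at
15 Hz, ~27,900 windows of 468 features. To keep a single-core run of the
complete protocol comfortable, the shipped configurations thin the
sequence set rather than the data: sequence stride 4 within trials
(~5,900 sequences), a stratified cap of 800 training sequences for the
100-epoch reference model, and 20-epoch / 500-sequence runs for the
placement comparison (CEWTA vs each single placement, median over three
seeds). These sizes are the package's own protocol choices; all of them
are plain `model_config()` arguments, and nothing prevents running the
full sequence set.

## Numerical choices and edge cases

* Rotations are represented as unit quaternions (w, x, y, z); the
  quaternion-to-matrix map is the closed form pinned term-by-term by
  tests, and R(q) = R(−q) (double cover).
* TRIAD refuses zero or (near-)parallel reference vectors; the
  parallel tolerance is relative to |V_mag|.
* Window statistics use the population (1/N) normalization for σ, so
  MAD ≤ σ always (Cauchy–Schwarz), and a constant window gives
  (c, 0, 0, 0).
* Streams shorter than one window yield zero windows, not an error;
  trials shorter than one sequence contribute zero sequences.
* The stratified splitter guarantees at least one trial of every
  activity on each side whenever an activity has ≥2 trials.
* CSV round trips are exact to 1e−9; model persistence round-trips
  bit-identically.

## Known limitations

* The LSTM is a from-scratch RcppArmadillo implementation; it trains on
  one CPU and has no GPU path, dropout, or hyperparameter search.
* Magnetic disturbance rejection and hard/soft-iron calibration are out
  of scope; the common-field assumption is built in.
* Synthetic headline numbers are not comparable to results on the
  private real dataset; only structural and directional properties
  carry over (e.g. that more placements do not hurt, and that the chest
  is the strongest single placement).
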