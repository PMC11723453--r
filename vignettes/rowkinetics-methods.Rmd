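---
title: "Estimating rowing kinetics from kinematic sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rowing kinetics from kinematic sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Force and power profiles are the backbone of rowing performance analysis:
the handle or gate force curve, its peak timing, and the split of total
power across legs, trunk, and arms characterize a rower's technique.
Measuring them directly requires instrumented oarlocks, foot stretchers,
and handle strain gauges — expensive hardware that must be swapped into
each boat or ergometer. This package implements an alternative: estimate
the six kinetic target sequences

* horizontal foot-stretcher force `Ff_x` (N),
* handle/gate propulsive force `Fh_x` (N, port+starboard sum on the boat),
* handle/gate power `Ph_x` (W),
* arm, trunk and leg powers `Pa`, `Pt`, `Pl` (W)

from *kinematic-only* sensing — cable position sensors (handle, chest,
seat) on the ergometer at 150 Hz, and body-worn IMUs, oar-angle sensors,
and GPS on a scull boat interpolated to 100 Hz — using a
sequence-to-sequence LSTM trained against sessions where the forces were
measured once with the full setup.

Because the human dataset that motivated this design is not publicly
available, the package ships a first-class synthetic session generator
with exact ground truth, so every stage — preprocessing, kinetics,
features, training, evaluation — is testable end to end.

## Kinetic target computation

On the ergometer, with cable positions `Xh` (handle), `Xc` (chest) and
`Xs` (seat), arm length and trunk opening are `Xa = Xh - Xc` and
`Xt = Xc - Xs`; leg extension is `Xs` itself. Velocities are time
derivatives, and the powers follow the standard segment decomposition:
`Ph_x = Vh*Fh_x`, `Pa = Va*Fh_x`, `Pt = Vt*Fh_x`, `Pl = Vl*Ff_x`. Because
`Va + Vt + Vl = Vh` identically, the decomposition closes
(`Pa + Pt + Pl = Ph_x`) whenever the handle and foot forces agree
samplewise; this identity is used as a regression test.

On the boat, the power transferred to the oars is, per side,
`Ph = (Fh_x*li*cos(theta) + Fh_y*li*sin(theta)) * dtheta/dt`, summed over
port and starboard, where `li` is the inner lever (gate-to-handle
distance). `li` is rigging-dependent and not part of the sensor record;
the default of 0.88 m is a typical scull inboard and can be overridden
per session. Trunk and leg powers use the IMU-derived horizontal
velocities in the boat frame: `Vt = V_It - V_Ip` (thoracic minus pelvis)
and `Vl = V_Ip - l_Ip * dtilt/dt * cos(tilt)` with `l_Ip = 0.15` m from
pelvis sensor to seat, giving `Pt = Fh_x * Vt` and `Pl = Ff_x * Vl`.
Arm power closes the balance: the total power a rower produces equals the
oar power plus the power spent accelerating the body, so with a
three-segment body model

```
Pa = Ph + (Ff_x - Fh_x) * V_boat - Pt - Pl .
```

One definition deserves an explicit note: the boat trunk velocity is
implemented as the *difference* `V_It - V_Ip` of the thoracic and pelvis
IMU velocities. Notation for this quantity is easy to mis-set (a juxtaposed
product of two velocities would be dimensionally impossible), so we state
the choice prominently: the difference is the only reading consistent with
the ergometer trunk definition (the derivative of `Xc - Xs`) and with the
structure of the leg-velocity correction.

## Preprocessing

* **Drift-removed integration.** IMU accelerations are integrated
  (cumulative trapezoid) and high-pass filtered at 0.1 Hz to remove
  integration drift. The filter is a zero-phase 2nd-order Butterworth
  (order and family are our choice; zero-phase so that no group delay
  corrupts synchronization), applied with mirror padding of twice the
  dominant time constant to suppress edge transients.
* **GPS/IMU synchronization.** The GPS boat velocity and the
  accelerometer-derived velocity are filtered identically and aligned by
  maximizing normalized cross-correlation over ±5 s; a peak correlation
  below 0.5 raises `sync_failed`. Boat speed records contain both a
  periodic within-stroke oscillation and slower stroke-to-stroke
  variation; the latter is what makes the correlation peak unique rather
  than periodic, which is why the synthetic generator models it (see
  below) and why synchronization should be run on records of a few dozen
  strokes rather than a handful.
* **Cycle segmentation.** Finish events are local maxima of the handle
  position (ergometer) or starboard oar angle (boat); the catch is the
  minimum in between; cycles run finish-to-finish with 0-based half-open
  index windows. Peak detection requires prominence ≥ 20% of the channel
  range and spacing ≥ 60/50 s (50 spm taken as the fastest plausible
  rate); these two constants are our choice, made once. Cycles outside
  1–5 s are discarded, as are cycles containing NaNs or |z| > 6 samples
  in any required channel (the artifact rule — which samples count as
  artifacts — is this package's own choice).
* **Effective drive phase.** Within each cycle the drive window opens
  when the measured handle/gate force exceeds 20 kgf and closes when it
  drops below 10 kgf. Internally everything is SI, so the thresholds are
  converted once with g = 9.81 m/s²: 196.2 N on, 98.1 N off.
* **Differentiation.** Central differences with one-sided edges. For
  measured (noisy) channels the pipeline low-pass filters at 10 Hz before
  differencing — rowing kinematics live well below 8 Hz, so this removes
  amplified sensor noise without touching signal content. Tests that
  exercise exact analytic identities run without smoothing.

## The synthetic session generator

The generator is phenomenological: it does not model flywheel or blade
hydrodynamics, but reproduces the structural features the estimator
relies on:

* **Phase structure.** Each cycle is recovery-then-drive between finish
  events, with drive fraction ~0.35–0.45. Segment excursions are smooth
  raised-cosine steps staggered legs → trunk → arms in the drive and
  arms → trunk → legs in the recovery; legs start moving exactly at the
  catch and arms stop exactly at the finish, so the summed handle
  position has strict extrema at the stroke events.
* **Force pulses.** Handle/gate force is zero throughout the recovery
  (noise clipped at zero — a chain or gate cannot push back) and follows
  a piecewise raised cosine during the drive with its peak at a
  controllable fraction of the drive; that fraction maps directly onto
  the measured time-to-peak, which is what makes technique-determinant
  recovery testable. A per-subject sharpness exponent makes the pulse
  peakier or flatter (driving mean-to-peak), and the foot-stretcher pulse
  leads the handle pulse by a per-subject lag with a per-subject
  amplitude ratio.
* **Movement style.** Subjects differ not only in timing offsets but in
  shape: each segment's drive excursion is time-warped by a per-subject
  skew exponent (early- vs late-accelerating legs, trunk, arms), and the
  legs/trunk motion occupies a per-subject fraction of the drive. These
  shape parameters are what spread the segment-power determinants (M2P,
  WR) across subjects — mirroring the variety of segment-involvement
  strategies seen in real rowers — so that inter-subject discrimination
  has a real signal to find. Echoing what is reported for human rowers,
  the trunk-power work ratio remains the least discriminable determinant
  on our benchmark.
* **Kinematics→force coupling.** Peak force scales with the subject's
  mass and with each cycle's speed (amplitude jitter × inverse duration),
  so the kinematic inputs genuinely carry the force information the
  network is supposed to learn; without this the learning tests would be
  vacuous.
* **Jitter and noise.** Cycle durations jitter ±3% and amplitudes ±5%.
  Measurement noise defaults (multiplied by `noise_sd`): 0.5 mm on cable
  positions, 2–3 N on forces, 0.05 m/s² on accelerations, 0.01 rad/s on
  gyros, 0.05 m/s on GPS speed, 5 mrad on oar angles — plausible scales
  for the respective sensor classes, chosen once.
* **Boat specifics.** Oar angles sweep −0.95 to +0.55 rad with minima at
  the catch. Boat speed is 4.5 m/s ± a 0.45 m/s within-stroke
  oscillation plus a 0.2 m/s SD band-limited (≤0.5 Hz) meander
  representing effort/wind/water variation; the GPS record is generated
  with margin beyond the IMU window so a planted clock offset samples
  real signal rather than padding. Body IMU accelerations are exact
  derivatives of the segment velocities used in the ground-truth
  equations, so the kinetics inversion is exact before noise.
* **Subject sampling.** Heights and masses are drawn near 1.85 ± 0.05 m
  and 79 ± 6.7 kg (boat) and 1.855 ± 0.071 m, 77.4 ± 7.0 kg (ergometer);
  stroke rates near the cohorts' session averages (32.5 spm boat,
  35.8 spm ergometer). Technique parameters (force peak position
  0.3–0.5, drive fraction 0.35–0.45, segment timing offsets) spread
  between subjects far wider than the within-subject cycle jitter, so
  determinant-based discrimination has something real to discriminate.
  One quarter of subjects carry an early-arm-peak "technical fault" that
  produces a contiguous negative arm-power segment in the drive.

Ground truth is computed from the noise-free channels *through the same
kinetics code path* used for measured targets (including the drift-removed
integration on the boat), so with `noise_sd = 0` target recomputation
reproduces truth to machine precision — a self-consistency invariant the
test suite asserts at 1e-9.

What the generator does **not** emulate: real curve-shape idiosyncrasies,
ergometer frame oscillation, blade–water interaction, wireless packet
loss, or inter-session sensor placement drift. Passing the synthetic
recovery tests therefore demonstrates that the pipeline's machinery is
correct and that the estimator can recover kinetics when the signal is
present — not that the specific error percentages transfer to human data.

## Features and normalization

Inputs are kinematics-only; a name blacklist asserts that no measured
force or power sequence can enter the feature path. The ergometer uses 16
channels (three positions, four velocities, three accelerations, and six
per-cycle scalars); the boat uses 18 (gate angular velocity, boat
velocity/acceleration, three IMU horizontal velocities, six
first-principal-component projections of IMU acceleration and angular
rate, and six scalars). Per-cycle scalars (height, mass, previous/current
drive durations, previous-stroke maxima and timing) enter the sequence
model as constant channels — the simplest mechanism that preserves the
stated channel counts. PCA for the 1PCA channels is fitted per IMU per
session with the sign fixed by a positive loading on the forward axis.
All channels (inputs and targets) are z-normalized with statistics fitted
on training cycles only; predictions are de-normalized before any metric
is computed.

The "time from maximum handle speed to the catch" scalar is computed from
the previous stroke's speed maximum to the current catch: the flywheel
spins down during the recovery, so this interval proxies the resistance
felt at the next catch.

## The sequence model

The regressor is a vanilla sequence-to-sequence LSTM implemented in
C++ (Armadillo): dense `nI → nI`, one LSTM layer, dropout, dense
`→ 6`, per-timestep squared-error loss. Cycles are variable-length
sequences in absolute time (not time-normalized); minibatches of 32 pad
to the longest member and mask the loss on padded frames (a property
test asserts padded frames carry zero gradient). Batches are assembled
after sorting by length to keep padding small — an efficiency choice with
no semantic effect. Training uses Adam (lr 0.001), up to 10000 epochs,
early-stopped when 20 epochs pass without improvement in the validation
full-cycle RMSE ("improvement" = any decrease, no minimum delta); the
weights from the best validation epoch are returned. Initialization is
Glorot-uniform with unit forget-gate bias; all randomness (init, batch
order, dropout) derives from explicit seeds, and runs are bit-reproducible
given a seed. Gate activations use a range-reduced polynomial exponential
(relative error < 3e-11), verified against finite differences in the test
suite.

Hyperparameter search samples units log-uniformly in [10, 500] and
dropout from {0, 5, 10}%, scoring each trial by the mean drive-phase MAE
over the six de-normalized targets on an 80/20 validation split; the
number of trials defaults to 20 and is configurable. The 80/20 split is
random by cycle, stratified by subject (a flag switches stratification
off), and the search objective averages the six targets with equal
weight — both are this package's choices among reasonable alternatives.

## Evaluation

Reconstructed and measured sequences are compared over the effective
drive phase, linearly interpolated onto 50 frames. The drive window is
always detected from the *measured* force so both sequences share one
window. Per target:

* `MAE` — mean |error| over all validation cycles and frames;
* `cMAE` — mean |cycle-averaged residual|: the error of the average
  curve, which cancels cycle-to-cycle noise (`cMAE ≤ MAE` always);
* normalized versions divide by the mean measured 50-frame curve, pooled
  over validation cycles (per-cycle normalization would differ slightly;
  we normalize by the pooled mean).

Technique determinants are computed over the *entire* catch-to-finish
drive (not the threshold window): T2P (peak instant, % of the window),
M2P (100·mean/max), WR (100·area before peak / total area, trapezoidal;
plateau peaks resolve to the first maximum index). Determinant
recoverability is quantified with two-sample pooled-variance t-tests at
α = 0.05 (a Welch flag is available): intra-subject accuracy `As` is the
percentage of subjects where measured and estimated determinants are
statistically indistinguishable; inter-subject accuracy `Ap` is the
percentage of subject pairs where the measured-vs-measured and
estimated-vs-estimated test decisions agree. No multiple-testing
correction is applied across the pair matrix; the pairwise accuracies
are descriptive, not confirmatory.

## Problem sizes and numerical choices

The package's reference synthetic benchmark is 12 ergometer subjects × 80
cycles (seed 1), trained with 64 LSTM units. The 80/20-split model trains
to early-stopping convergence (patience 15, which stops around epoch 85
and reaches ~2.6% mean drive-phase normalized MAE, against a 10%
assertion bound); leave-one-subject-out runs its twelve folds at a cap of
10 epochs (patience 5) to keep the full suite in minutes, alongside a
like-for-like 80/20 model at the same cap so the generalization-gap
comparison is also epoch-matched (the out-of-subject error is several
times larger either way). The acceptance script uses
a somewhat smaller cohort (8 × 40 ergometer, 6 × 40 boat) under the same
logic. Synchronization checks run on 30-stroke logs, reflecting how GPS
alignment is done in practice on long records.

Degenerate inputs are handled explicitly: zero-variance PCA input raises
`degenerate_signal`; a zero mean curve raises `degenerate_normalizer`;
all-zero determinant curves raise `no_peak`; force never crossing the
onset threshold raises `no_drive_detected`, and a drive that never
terminates closes at the cycle end with a warning. Zero-spread feature
channels (constant scalars in a single-subject dataset) normalize with
sd = 1 under a warning.

## Known limitations

* The simulator is a structural stand-in, not a validated biomechanical
  model; absolute error levels on synthetic data do not transfer to human
  recordings.
* Leave-one-subject-out error is dominated by subject-level technique and
  anthropometry shift — the expected behaviour for a cohort of a dozen
  subjects — but its magnitude here reflects the generator's
  inter-subject spread, not human variability.
* The boat pipeline assumes port/starboard gate sensors report the
  propulsive (x) component in the boat frame and that IMU velocities are
  expressed in the boat frame after sensor fusion.
* Only single-layer LSTMs are implemented; multi-layer stacks,
  GPU training, and attention variants are out of scope.
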