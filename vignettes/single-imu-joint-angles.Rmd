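---
title: "Estimating hip, knee and ankle angles from a single shank IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hip, knee and ankle angles from a single shank IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sagittal-plane hip, knee and ankle angles during walking are clinically
useful (injury risk, rehabilitation tracking), but the gold-standard
optical motion capture (MoCap) that measures them is confined to the lab.
A single inertial measurement unit (IMU) strapped to the lateral shank is
cheap and wearable, and a low sampling rate (23 Hz here) keeps battery
consumption compatible with all-day use — at the price of very few samples
per gait cycle (about 24 at typical cadence). `gaitlstm` implements a
sequence-learning pipeline that maps the shank IMU's nine channels
(pitch/roll/yaw attitude, 3-axis gyroscope, 3-axis accelerometer) to the
three joint angles, and an evaluation harness that quantifies how well
that mapping transfers across gait cycles and across people.

The pipeline is:

1. **Signal conditioning** — reference kinematics are low-pass filtered
   (zero-phase 4th-order Butterworth, 4 Hz cutoff); IMU channels are
   median-smoothed (5-sample window); per gait cycle, the 60 Hz kinematic
   labels are resampled to the cycle's IMU sample count.
2. **Feature selection** — each channel is scored per joint by the
   absolute Pearson correlation with that joint's angle over the training
   cycles; scores are normalised by the per-joint maximum and channels
   above 30 % relative importance are kept; the union over the three
   joints feeds one multi-output model.
3. **Regression** — a single-layer LSTM (hidden size 50, tanh cell
   activation) reads sliding windows of 5 consecutive IMU samples and
   emits the three joint angles in degrees at the window's last sample,
   trained with Adam (learning rate 0.001, batch 256) on the weighted
   multi-joint loss
   \[
   L = A\,\mathrm{MSE}_{hip} + B\,\mathrm{MSE}_{knee} +
       C\,\mathrm{MSE}_{ankle},\qquad (A,B,C) = (3,1,4).
   \]
4. **Evaluation** — 5-fold cross-validation under three data divisions:
   *within-one-subject* (train and test cycles from the same person,
   16/4 cycles per fold), *intra-subject* (cycles pooled over everyone,
   80/20), and *inter-subject* (whole held-out people, e.g. 24/6 of 30).
   Per joint: RMSE (deg), per-cycle NRMSE (%) and pooled R².

Because the motion-capture dataset the method was developed on is not
publicly deposited, the package ships a synthetic cohort generator with
the same acquisition geometry and statistics, which is what all tests and
the acceptance script run on.

# The synthetic cohort generator

## Joint-angle templates

Each joint's trajectory over one gait cycle is a 6-harmonic Fourier series
on normalised phase $u \in [0,1)$:
$f(u) = a_0 + \sum_{k=1}^{6} a_k \cos(2\pi k u) + b_k \sin(2\pi k u)$.
The Fourier form makes angles and all derivatives exactly periodic, so
consecutive cycles join smoothly and angular velocity integrates to zero
over a cycle. The shipped default templates are normative adult walking
curves (hip roughly $-10$ to $32^\circ$, knee $4$ to $63^\circ$ with the
loading and swing peaks, ankle $-18$ to $15^\circ$ with the push-off
plantarflexion trough). Their phase origin is deliberately placed at the
within-cycle peak of the shank angular velocity, so the optional
gyro-peak cycle detector (`detect_cycles_gyro`) and the simulator's exact
boundaries agree by construction.

Per subject, each template is perturbed by an amplitude scale
($\mathcal N(1, 0.08)$), an additive offset ($\mathcal N(0, 2^\circ)$) and
a phase shift ($\mathcal N(0, 0.02)$ cycles). These three knobs are what
make people differ, and hence what makes the inter-subject scheme harder
than the intra-subject scheme.

## Subject profiles

Walking speed and cadence are drawn from the emulated cohort's statistics
(speed $1.27 \pm 0.13$ m/s, cadence $113.87 \pm 7.32$ steps/min); stride
length is then *derived* from the identity
$\text{speed} = \text{stride} \times \text{cadence}/120$ (a stride is two
steps), so the identity holds exactly for every subject. Thigh and shank
lengths are $\mathcal N(0.42, 0.02)$ and $\mathcal N(0.41, 0.02)$ m; the
sensor sits 0.10 m below the knee along the shank. Draws are clipped to
physical floors (speed 0.5 m/s, cadence 60 steps/min, segment lengths
0.2 m) with a logged message.

## Planar forward kinematics

The model is strictly sagittal with the trunk vertical: thigh inclination
from vertical equals hip flexion and shank inclination is
$\varphi = \text{hip} - \text{knee}$. The hip point advances at constant
speed with small oscillations at step frequency (defaults 2 cm vertical,
1 cm fore-aft — typical of normative gait). The sensor position follows
from segment geometry; its acceleration is obtained by central finite
differences on a dense internal grid (20 × the IMU rate, i.e. 460 Hz, so
the finite-difference error is far below sensor resolution). Specific
force is (acceleration − gravity) rotated into the sensor frame
(x longitudinal-distal, y anterior, z mediolateral) and expressed in g;
the mediolateral gyro reads $d\varphi/dt$. At rest the longitudinal axis
reads $-1$ g (it points down; the reaction is up).

Channels that the planar model cannot inform are synthesised as
*realistically redundant* inputs: roll is a small ($2^\circ$)
gait-phase-locked oscillation, the x/y gyro and z accelerometer are weak
cross-talk oscillations whose phases are drawn per subject (mounting
differences), and yaw is pure sensor noise. This gives the feature
selector genuine work: informative channels (pitch, z-gyro, x/y
acceleration, roll) must be separated from channels that correlate within
a subject but not across a cohort (cross-talk) and from pure noise (yaw).
The ankle deserves note: in a rigid planar model the ankle angle does not
affect a shank-mounted sensor at all, so the simulated ankle is only
*statistically* coupled to the IMU through the shared gait phase —
mirroring the real situation, where ankle motion is inferred rather than
measured. This is why ankle accuracy degrades fastest from the
within-one-subject to the inter-subject scheme.

## Acquisition model

IMU channels are sampled at 23 Hz, kinematics at 60 Hz. Gaussian channel
noise defaults to 0.02 g (accelerometer), 1.0 deg/s (gyro) and 0.5 deg
(attitude) — chosen once so that end-to-end accuracy on the default cohort
lands in a realistic range rather than at R² = 1. Accelerometer and gyro
samples are quantised to the instrument resolutions (0.01 g, 0.05 deg/s).
Cycle durations carry 3 % multiplicative jitter. Cycle boundaries
(phase-zero crossings) are recorded exactly in both streams; segmentation
of real recordings is out of scope, though `detect_cycles_gyro` provides
a peak-picking utility validated against the simulator's exact
boundaries.

What the generator does **not** emulate: 3-D (frontal/transverse)
kinematics, soft-tissue artefact, sensor-to-segment misalignment, foot
events, ground-reaction forces, fatigue or speed drift within a session,
and pathological gait. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's machinery is correct and that its
relative orderings (scheme difficulty, feature informativeness) behave as
the underlying geometry dictates — not that the absolute accuracy numbers
transfer to real patients.

# Numerical and design choices

**Zero-phase filtering.** The reference kinematics are filtered offline,
so the package uses forward–backward (zero-phase) application; a causal
filter would delay labels relative to IMU samples. The filter is designed
with `signal::butter`; the application step implements odd-reflection
padding with steady-state initial conditions, so a constant signal passes
through bit-exactly and edge transients are suppressed.

**Label alignment.** After filtering, labels must be placed on each
cycle's IMU sample grid. The default interpolates the filtered kinematic
streams at the IMU sample *instants* ("time" alignment): a label is the
joint angle at the exact moment its feature row was sensed. The simpler
convention of mapping the cycle's kinematic samples onto a normalised
0–1 grid (`label_alignment = "normalized"`, via `resample_cycle_labels`)
is also provided, but because a cycle's first IMU sample falls up to one
sample period (1/23 s) after the true cycle start, it displaces labels by
up to one sample of phase — about 3° RMS at the knee, whose angular speed
peaks near 400 deg/s. That displacement is an artefact of label
bookkeeping, not of the sensor, so the time-aligned construction is the
default.

**Normalisation scope.** Min–max statistics (inputs scaled to 0–1) are
fitted on the training split of each fold and applied unchanged to test
data, without clamping; fitting on pooled data would leak test
information into training. Output angles are *not* normalised — the
network regresses degrees directly.

**Read-out head and optimisation.** The LSTM cell is standard (input,
forget and output gates, tanh cell activation); the head is a single
linear layer from the hidden state to the three angles. Two facts shape
the training procedure. First, the weighted loss is separable over
joints, so for any fixed trunk the optimal head is an ordinary per-joint
least-squares problem. Second, Adam's per-parameter step is bounded by
the learning rate, so with learning rate 0.001 and a few hundred updates
the head could never climb from an order-one random initialisation to
degree-scale outputs. `train_lstm` therefore solves the head in closed
form (ridge regression, $\lambda = 10^{-3}$) on the initial hidden states
before the first epoch — a reservoir-style warm start — and re-solves it
after the last epoch, which is exact coordinate minimisation of the
training objective in the head parameters. Adam trains everything in
between at the prescribed hyperparameters. Plain end-to-end gradient
training is available via `ridge_readout = FALSE`.

**Hyperparameters.** Defaults are one layer, batch 256, hidden 50,
Adam at 0.001, sequence length 5, 500 epochs, tanh activation and loss
weights (3, 1, 4). The reference configuration reports hidden size 50 in
its hyperparameter table but 10 in the accompanying text; the table value
is the default here and both are reachable through `hidden_size`. Windows
are left-padded by replicating the first sample so every label sample
gets a prediction (the per-cycle NRMSE denominator needs complete
traces); `drop_partial = TRUE` gives the alternative. The hidden state is
reset per window — windows are independent samples and never cross cycle
boundaries. There is no early stopping; epochs are simply configurable
for desk-scale runs. All randomness (initialisation, shuffling) flows
from one run seed, and fold construction uses a separate split seed.

**Metrics.** RMSE is pooled per fold and joint; NRMSE is computed per
cycle — 100 × RMSE / (max − min) of the *predicted* trace, the
convention of the reference text, with the reference-range variant behind
`denominator = "reference"` — and averaged over test cycles; R² is pooled
over a fold's test samples. A constant denominator trace makes NRMSE
undefined for that cycle; it is flagged and excluded from the average.
Under the within-one-subject scheme each subject's five folds are
averaged first, then subjects are averaged with equal weight.

**Feature selection.** Correlations are computed on preprocessed but
unnormalised features (Pearson's r is affine-invariant, so this cannot
change the ranking), pooled over all training-cycle samples, separately
per fold inside cross-validation — selection is part of the training
pipeline and must not see test data. The threshold is strict
("more than 30 %"), and the returned union follows the canonical
9-channel order so column layouts are reproducible.

# Problem sizes in the shipped tests and acceptance script

The test suite and `scripts/acceptance.R` run at sizes chosen to exercise
every code path on a laptop-class single core: feature-selection
recovery uses 20 full-size cohorts (30 subjects each, preprocessing and
correlation only); parameter recovery trains the within-one-subject
scheme on a noise-free 10-subject × 16-cycle cohort at 150 epochs; the
scheme-ordering comparison runs all three schemes on a default-noise
10-subject cohort at 60 epochs. The acceptance script reports the
scheme × joint grid from the same desk-scale configuration. These
reduced-epoch runs are converged enough for the properties they check
because the ridge-solved head removes the long scale-climbing phase of
training; the 500-epoch default remains the reference configuration for
full-size runs.

# Known limitations

- The simulator is planar and trunk-vertical; real pitch attitude mixes
  in frontal-plane lean, and real accelerometers see soft-tissue wobble.
- Ankle estimates rest entirely on phase coupling; any intervention that
  decouples ankle motion from shank motion (orthoses, pathology) breaks
  the premise, in the simulator as in the field.
- Gait-cycle segmentation of real data is the user's responsibility;
  the bundled detector assumes one dominant mediolateral-gyro peak per
  stride.
- Training is CPU-bound pure R; it is comfortable at cohort scale
  (hundreds of cycles) but not meant for datasets orders of magnitude
  larger.
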