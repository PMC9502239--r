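---
title: "Detecting Parkinson's disease from free-living wrist sensor data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdwear methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Parkinson's disease (PD) alters motor behaviour — bradykinesia (slowed,
attenuated movement), gait changes and 4–9 Hz tremor — and these signatures
surface most clearly while a person walks. A wrist-worn watch recording
triaxial accelerometer and gyroscope streams at 100 Hz during ordinary daily
life captures walking many times per day, but without any activity labels:
the data are "open world". `pdwear` implements a pipeline that (1) isolates
5-second *walk-like events* from unconstrained recordings with deterministic
signal-processing rules, (2) classifies each event as PD or healthy control
(HC) with a small one-dimensional convolutional network, and (3) aggregates
event decisions into one diagnosis per day by majority vote. Evaluation uses
leave-one-subject-out cross-validation (LOGO-CV) with the first ten recorded
days, plus temporal holdout blocks one to three months later.

Real cohorts of this kind are access-restricted, so the package ships a
synthetic cohort generator that emulates the free-living structure of such
recordings with tunable PD effect sizes; every stage of the pipeline is
exercised end-to-end against that generator's ground truth.

# Walk-like event detection

Raw 100 Hz recordings are down-sampled to 20 Hz and cut into non-overlapping
5-s windows (100 samples) that never straddle a calendar-day boundary, so
daily votes are well defined. Each window passes two gates:

1. **Dynamic gate (accelerometer).** For each subject, an adaptive threshold
   is computed once from the first recorded day: half the maximum over that
   day's windows of the dominant-axis detrended mean absolute value (MAV).
   A window is *dynamic* iff its dominant-axis accelerometer MAV strictly
   exceeds the threshold. Dominant-axis selection (argmax of per-axis MAV,
   ties to the lowest axis index) makes the rule insensitive to how the
   watch is worn.
2. **Spectral gate (gyroscope).** For dynamic windows only, the Welch power
   spectral density of the dominant gyroscope axis is compared between the
   walking band (0.6–2 Hz) and the rest of the non-DC spectrum. The window
   is *walk-like* iff the mean band PSD strictly exceeds the mean
   out-of-band PSD **and** is at least the absolute power floor of
   100 (deg/s)²/Hz.

Design choices a maintainer should know about:

* **Detrending before MAV.** The per-window mean is subtracted before the
  absolute value. Without this, gravity puts a resting wrist at ~1 g MAV and
  the half-of-max rule stops measuring movement. This is the load-bearing
  interpretation of "mean absolute value" here.
* **Welch parameters.** 2-s Hann-tapered segments with 50% overlap and
  per-segment mean detrending (one-sided density normalization). 2 s gives
  0.5 Hz resolution — enough to separate the walking band from its
  complement, while still averaging three segments per window. The
  estimator matches the usual scientific-Python conventions bin for bin.
* **"Higher than the rest" as means, not sums.** Band and complement have
  different bin counts; comparing means avoids a size bias. The DC bin is
  excluded from the complement.
* **Strictness.** Strict `>` for the dynamic gate and band dominance;
  `>=` for the power floor.
* **Both thresholds are computed** (accelerometer and gyroscope) but only
  the accelerometer threshold gates dynamism; the gyroscope value is kept
  in `subject_thresholds()` output for audit.
* **Day boundaries** use a configurable fixed UTC offset (default +00:00);
  gaps longer than 1 s split a recording at read time (non-wear and
  charging are not otherwise modelled).
* **Down-sampling** applies a zero-phase Hamming-window FIR low-pass with
  cutoff at 0.45× the target rate before taking every k-th sample; the
  filter order is chosen so the stopband (≥ 40 dB attenuation) begins at the
  target Nyquist. A symmetric kernel applied centred is exactly zero-phase
  in one pass.

# The event classifier

Each walk-like window (6 channels × 100 samples) is classified by a 1D CNN:
four convolutional blocks — kernel 5, stride 2, no pooling, channels
8/16/32/64, each block conv → L2 penalty → batch normalization → ReLU —
followed by dropout 0.5, flatten (7 × 64 = 448) and a 2-unit softmax head
trained with cross-entropy (the two-class softmax form of binary
cross-entropy) under Adam. Temporal lengths halve per layer
(100 → 50 → 25 → 13 → 7 with "same" padding) and the receptive field of one
final-layer step is 61 input samples (~3 s), via the recurrence
r ← r + (k−1)·(product of earlier strides).

The network, its gradients and the optimizer are implemented in the package
itself (im2col convolutions over BLAS matrix products); training is
deterministic given the seed.

Choices and their rationale:

* **Input normalization.** Each window's channel means are removed and each
  sensor triplet is rescaled to unit RMS before a per-channel scale
  (estimated on training windows only) is applied. Gravity direction and
  gyro bias are subject- and orientation-specific DC levels, and absolute
  movement amplitude varies more between subjects than between classes in a
  small cohort; both are classic shortcut features that a subject-held-out
  evaluation must not reward. Events are therefore classified on waveform
  shape and spectral texture, in normalized units.
* **Class weighting (default on).** A LOGO fold is imbalanced by
  construction (one subject's windows are removed). With no class signal an
  unweighted fit collapses to the training-majority class — which for the
  held-out subject is systematically the *wrong* class, so a null experiment
  would read as 0 accuracy rather than chance. Inverse-frequency weights
  keep the no-signal fixed point at p ≈ 0.5. Set
  `cnn_config(class_weights = FALSE)` to disable.
* **Early stopping.** In cross-validation each fold trains on all training
  subjects and uses the held-out subject's first-10-day windows as the
  validation set for early stopping and for the reported validation
  accuracy; the temporal-holdout blocks months later are the untouched test
  data. The best validation-loss weights (including the pre-training state)
  are restored after `patience` epochs without improvement. Patience
  defaults to 12: on folds whose held-out subject sits near the edge of the
  cohort's cadence distribution the validation loss is noisy and can
  plateau or rise for ~10 epochs before descending, and a short patience
  freezes the pre-training weights.
* **Defaults not pinned by the architecture:** L2 coefficient 1e-4, batch 64,
  at most 50 epochs, Adam 1e-3, decision threshold 0.5 on the PD
  probability.

# Hand-crafted features and comparison classifiers

For the feature-based baselines each window yields 35 features: per sensor,
per-axis mean, variance, skewness and excess (Fisher) kurtosis plus the
maximum absolute amplitude across axes (13 × 2); and Hann-tapered
accelerometer band powers for 0–4 Hz, 4–9 Hz (the tremor range) and
9–10 Hz per axis (9). Band powers exclude the DC bin (the mean is already a
feature) and the three bands partition the non-DC spectrum exactly; with a
20 Hz analysis rate the "9 Hz and up" band is capped at the 10 Hz Nyquist.
Zero-variance axes report skewness and kurtosis 0.

Four classifiers run on these features under the identical LOGO folds:
logistic regression (`glm`), random forest, gradient-boosted trees
(`xgboost`) and an elastic-net-penalized logistic classifier
(`glmnet`, alpha = 0.5, lambda by seeded 5-fold CV). Features are
standardized with training-fold statistics for the linear methods.

# Evaluation protocol

* `make_logo_folds()` builds one fold per subject; training and validation
  windows come from each subject's first ten recorded days.
* `daily_majority_vote()` decides PD iff the PD fraction of the day's events
  is ≥ 0.5. The tie at exactly 0.5 goes to PD (favouring sensitivity); with
  continuous probabilities ties are essentially measure-zero.
* `temporal_holdout_eval()` scores each fold's model on its held-out
  subject's windows in 5-day blocks starting 30/60/90 days after that
  subject's first recording; blocks intersecting the training range are
  rejected, and missing blocks are reported absent, never imputed.
  Per-subject accuracies are reported both per event and per day.
* `walk_duration_summary()` converts walk-like window counts to daily hours
  (count × 5 s / 3600) and compares groups with Welch's unequal-variance
  t-test (the robust default among "t-tests").

# The synthetic cohort generator

`simulate_cohort()` generates labelled free-living days: rest (1 g gravity
along a slowly re-orienting direction plus sensor noise), non-walk dynamic
bursts (broadband noise plus an off-band 3–8 Hz tone), and walk bouts —
a quasi-periodic oscillation (fundamental plus one harmonic at 0.4
amplitude) on the gyroscope with matched accelerometer modulation. Bout
starts follow a Poisson-like process whose occupancy tracks
`walk_bout_rate × mean bout duration`; durations are log-normal (~57 s).
PD subjects express four effects, all tunable in `pd_effects`:

| effect | default | meaning |
|---|---|---|
| `amplitude_attenuation` | 0.6 | bradykinetic scaling of gait amplitudes |
| `tremor_amplitude` (gyro), `tremor_amplitude_acc` | 30 deg/s, 0.1 g | tremor tone at a per-subject 4–6 Hz frequency |
| `cycle_time_jitter_sd` | 0.08 (vs 0.02 HC) | cycle-to-cycle cadence irregularity |
| `bout_rate_factor` | 4.3/5.65 | reduced daily walking, matching the reported HC/PD daily-walking ratio |

Subject-level draws: mean step frequency uniform in 0.8–1.8 Hz, a
movement-vigor scale (log-normal, sd 0.15) multiplying gait and burst
amplitudes alike, and sensor orientations clustered around a canonical
wrist frame (`axis_spread = 0.4`). Bout-level draws: cadence varies ±7%
about the subject mean, gait/tremor axes wobble (`bout_axis_spread = 0.25`)
and phases re-randomize. These within-subject variations are what real
free-living gait has and lab-clean simulations lack; without them each
subject's fixed cadence, phase and axis mixture act as an identity
fingerprint, and a subject-held-out classifier is rewarded for memorizing
subjects rather than learning class structure. Effect sizes default to a
regime of roughly 90% single-event separability.

**What the generator does not model** — and hence what passing tests do not
show about real data: biomechanical gait detail (heel strikes, asymmetry),
diurnal and medication-cycle symptom fluctuation, activity context
(stairs, carrying loads), device non-wear patterns beyond simple gaps, and
real sensor artefacts. Results on this generator validate the pipeline's
mechanics and its statistical discipline, not clinical performance.

# Problem sizes and numerical notes

The packaged end-to-end experiments use 8 subjects (4 HC / 4 PD) with
12 recorded days plus 5-day blocks at days 30, 60 and 90, at 0.15 wear-hours
per simulated day — about 25 walk-like events per subject-day, roughly two
thousand training windows per fold. These sizes keep a full LOGO-CV with
per-fold CNN training comfortably reproducible on a single CPU while leaving
every statistical property of the full-scale design intact; the generator's
defaults (18 h wear, the published cohort composition of 4 HC and 7 PD)
remain the reference conditions for full-scale use.

Numerical details: batch-norm epsilon 1e-5, running-statistics momentum 0.9;
He initialization; early-stopping improvement threshold 1e-6; softmax
computed with the max-subtraction trick; the Welch and tapered-band-power
estimators floor nothing (PSDs are non-negative by construction); windows
shorter than one Welch segment raise an error rather than silently padding.
Degenerate inputs (constant windows, zero-variance axes, empty days,
single-class training sets) are either defined results (0 skewness, no
decision) or explicit errors, as documented per function.

# Known limitations

* The CNN is trained on CPU with modest cohort sizes; wall-clock scaling to
  hundreds of subjects would want a compiled backend.
* The walk-like detector's power floor of 100 (deg/s)²/Hz is inherited from
  tuning on an external labelled benchmark in the original design; its
  appropriate value depends on gyroscope units and mounting.
* Per-subject adaptive thresholds assume the first recorded day is
  representative; a first day spent mostly at rest would lower the dynamic
  gate for all later days.
* With cohorts this small, subject-level cross-validation accuracy has high
  variance; single-subject failures should be read as such, not as
  population error rates.
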