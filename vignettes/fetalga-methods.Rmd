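---
title: "Methods: gestational-age estimation and growth-restriction screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gestational-age estimation and growth-restriction screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fetalga)
```

## Overview and assumptions

`fetalga` estimates gestational age (GA) from two inexpensive signals — a
1D Doppler ultrasound (1D-DUS) audio recording of the fetal heart and a
both-arm maternal blood-pressure reading — and screens for possible
intrauterine growth restriction (IUGR) through the *error* of that
estimate. The chain of assumptions is:

* fetal heart-rate (FHR) dynamics mature with gestation: the baseline
  falls, beat-to-beat and long-term variability rise, accelerations become
  more frequent; maternal blood pressure rises through pregnancy;
* a regressor trained on normally grown fetuses therefore reads GA out of
  the 37-feature phenotype;
* a growth-restricted fetus at calendar month $m$ presents the phenotype
  of a *younger* fetus, so its GA is underestimated. With LMP-based dating
  as the reference, $\delta = \mathrm{GA_{LMP}} -
  \operatorname{median}(\widehat{\mathrm{GA}})$ is positive in the
  IUGR-suggestive direction, is inversely related to birth weight, and
  carries discriminative information about low birth weight (LBW).

GA is handled in whole months since the last menstrual period (range
6–9), the resolution at which such data are collected in the field; errors
convert to weeks with the $40/9$ weeks-per-month factor. LBW is defined by
sex-specific thresholds (2.64 kg male / 2.57 kg female) obtained by
mapping a national-survey $\le$ 2.5 kg percentile (14.3% / 16.33%) onto
the local weight distribution (`derive_lbw_threshold()`).

## FHR extraction

The recording is analysed in 3.75-s windows slid by 0.25 s (a 4-Hz
estimate stream). Per window:

* **quality surrogate** — the study this design follows used a trained
  classifier over {good, interference, silence, talking, low SNR}; here a
  transparent rule set stands in (near-zero RMS → silence; > 50% of
  spectral power within ±1 Hz of 50/60 Hz → interference; envelope
  autocorrelation peak < 0.3 → low SNR), and externally supplied labels
  are accepted verbatim. `talking` is only ever assigned externally.
* **rate estimation** — envelope = rectification followed by a 25-Hz
  moving-average low-pass; the envelope autocorrelation is searched over
  lags 0.25–1.0 s (240 down to 60 BPM). Because integer multiples of the
  fundamental period peak almost as high, the *shortest* lag whose local
  maximum reaches 85% of the band maximum is taken, with parabolic
  sub-sample interpolation; FHR = 60/period. A peak below 0.3 of the
  zero-lag value is deemed unreliable (`NA`).

Cleaning (`clean_fhr_series()`) removes estimates outside the inclusive
65–175% band of the mean of the two previously retained estimates (the
first two estimates have no history and are accepted), removes non-good
windows, and linearly interpolates each removed run up to the next
*stable segment* (five adjacent retained points spanning ≤ 10 BPM);
isolated estimates stranded between a removed run and the next stable
segment are treated as part of the run, which makes the interpolated
fraction equal the removed fraction and the operation idempotent.
Leading/trailing gaps are filled from the nearest stable value. Inclusion
screens: recording strictly longer than 10 min with ≥ 50% good windows;
blood pressure with arm differences < 15 mmHg and arm-mean SBP ≤ 130,
DBP ≤ 80 mmHg.

## Baseline, events, and the feature panel

The baseline is a two-pass filter bank: running medians of 16, 32, 64 and
128 s followed by a 60-s moving average, recomputed after clipping samples
deviating more than 10 BPM from the first pass. The 128-s stage is needed
because accelerations can last 45 s and would partially survive a 64-s
median; medians track monotone drift exactly, so slow trends are
preserved. The construction is shift-equivariant, reproduces constants to
numerical precision, and attenuates 15-BPM/15-s events to < 2 BPM.

Event detection follows the Dawes criteria at 4 Hz: a maximal run above
(below) the baseline lasting ≥ 15 s (60 samples) with at least one sample
≥ 15 BPM above (below) it. Minute validity is judged on the *baseline*
segment — a 10-BPM-bin histogram whose modal bin must exceed 40% of the
minute — so a minute is invalid only where the baseline itself is
unstable; events overlapping no valid minute are dropped. Runs are split,
not bridged, at baseline crossings.

The 37 features (canonical order: alphabetical within the linear,
non-linear, spectral and hemodynamic groups) are computed from the
interbeat sequence $T(i) = 60000/S(i)$ ms and the FHR trace. Notable
parameter choices, all visible as function defaults:

* epoch length 2.5 s → 24 epochs/min; STV/II/LTV per minute then averaged,
  LTI as the mean over 3-min segments of the interquartile range of
  $\sqrt{T_k(i)^2 + T_k(i-1)^2}$;
* PRSA capacities with both parameters at one collapse to the mean
  half-increment over anchor points — the only consistent reduction of the
  wavelet form at scale 1;
* ApEn with $m = 2$, $r = 0.1\,\mathrm{SD}$; Higuchi dimension with
  $k_{\max} = 5$; Rosenstein Lyapunov exponent (embedding dimension 1,
  lag 2, Theiler window 10, slope over the first 10 steps, per-sample
  units); tone–entropy on percentage differences with 0.5-point bins over
  ±20% (entropy in bits); the delayed mutual information with 16
  equiprobable bins, which at embedding dimension 1-per-coordinate
  averaging equals the lag-1 histogram MI — the estimator is pluggable;
* Welch spectra (Hann, 256-sample/64-s segments, 50% overlap) integrated
  trapezoidally over 0.03–0.15, 0.15–0.5 and 0.5–1 Hz;
* basal FHR as the mode of integer-rounded BPM outside events, ties broken
  toward the median;
* degenerate conventions: constant series give 0 for ApEn, Lyapunov,
  entropy, GMI, tone, II and the STV/LTV ratio; SV is computed as
  $0.002\,\mathrm{PP}$, the algebraic simplification of
  $\mathrm{CO}/\mathrm{MHR}$, making the identity exact in floating point.

## Modelling

Patients (never visits) are split into train/test sides, re-randomized
until a two-sided Wilcoxon test finds no significant train/test difference
for any feature (α = 0.05, capped at 1000 draws). Each cross-validation
iteration: ADASYN grows every month to the majority count (synthetic rows
are convex combinations of same-month neighbours, weighted toward class
borders; a month reduced to a single row in a training subset is
duplicated first, the only hull-consistent fallback); features are
standardized with balanced-training mean and population SD; a ranking is
recorded (mRMR with quartile-binned mutual information for the SVR,
summed split gain for the boosted trees); hyperparameters are tuned by an
inner 3-fold patient-grouped grid search; the held-out fold is predicted.
Fifty trials of five folds give 50 MAE vectors and 250 rankings; mean
ranks define the top-10/15/20 sets. Median/IQR and rank-order (binomial)
95% confidence intervals summarise the per-trial MAEs; regression targets
are the integer months, predictions are not rounded.

Grids: SVR $C \in \{2^{-3},\dots,2^{8}\}$ (step-1 exponents reach both
printed endpoints of the inconsistent step-2 listing),
$\epsilon \in \{2^{-10},\dots,2^{-5}\}$, $\gamma$ analytic (inverse median
pairwise squared distance over a seeded 70% subsample); Elastic Net mixes
$\lambda \in \{0.1,\dots,0.9\}$ with a 100-value path whose
smallest/largest ratio is $10^{-4}$ (the ratio, not the printed
$10^{-5}$ decrement, governs — they conflict); boosted trees over learning
rates $\{0.1, 0.25, 0.5, 1\}$, 100–550 trees, depths
$1..\lfloor\log_2(S-1)\rfloor$.

Final testing repeats 100 times with fresh ADASYN draws; the per-visit
**median** estimate across repetitions feeds the screening stage. Because
hyperparameters depend on the data far more than on the balancing draw,
`tune_once = TRUE` tunes on the first draw and reuses the result at
scale; the default re-tunes every repetition. The group comparison is the
rank-sum test between the per-repetition MAE distributions of the two
groups — repetitions share test visits, so this quantifies the stability
of the gap under balancing resampling rather than sampling of new
patients; the per-visit comparison is also reported.

The screening statistic is fitted against birth weight by iteratively
reweighted least squares with the Tukey bisquare loss (c = 4.685, ≤ 50
iterations, tolerance 1e-8); the ROC sweeps all distinct δ values with
half-credit ties (equivalently the Mann–Whitney statistic), which makes
the area insensitive to the strict/non-strict threshold convention.

## The synthetic cohort: what it emulates, and what it does not

Field recordings of this kind are not publicly available, so the
generator (`sim_profile()`, `simulate_cohort()`) defines the study
conditions:

* FHR baseline 143 BPM at month 6 falling 4.4 BPM/month (≈ 15 BPM across
  the last trimester), subject SD 5 BPM, rejection-sampled to stay within
  110–160 BPM;
* epoch-scale (2.5 s) interbeat noise as an AR(1) process (φ = 0.5)
  calibrated so the expected short-term variability is 5 ms at month 6,
  rising 1 ms/month (subject SD 0.8 ms);
* trapezoidal accelerations/decelerations (20–45 s, 17–25 BPM peak, 3-s
  ramps) at 0.10→0.25 and ~0.02–0.03 events/min across months 6→9 — every
  planted event is Dawes-detectable by construction;
* maternal SBP/DBP/MHR 103/64 mmHg, 82 BPM at month 6 with slopes
  +2/+1.5 mmHg and +2 BPM per month, inter-arm jitter capped well below
  the 15-mmHg screen;
* Doppler envelopes as raised-cosine bursts of a 500-Hz carrier at beat
  times from the integrated instantaneous rate, additive white noise at a
  10-dB default SNR, and a dropout fraction of 3.75-s blocks replaced by
  silence or noise (ground-truth labels retained). The canonical field
  digitization rate is 44.1 kHz; synthetic envelopes default to 4 kHz,
  which preserves all structure the estimator uses at a fraction of the
  cost;
* birth weights Normal(3.1, 0.3) kg for the normal group and
  Normal(2.3, 0.4) kg for the LBW group, truncated at 0.5 kg and at the
  sex-specific threshold so the group label and weight flag agree (the
  truncation shifts group means by a few hundredths of a kg);
* visits skewed toward late gestation (5/25/28/42% across months 6–9;
  90% of patients one visit, 9% two, 1% three);
* IUGR as a **maturation lag**: the LBW group's GA-dependent parameters
  at month $m$ are evaluated at $m - \mathrm{lag}(m)$ with lag
  0/0.5/1.0/1.5 months at months 6–9. A lag (rather than an additive
  offset) reproduces the observed pattern of underestimation growing
  toward term. The lag schedule is a tunable emulation device, not an
  empirical claim.

Default problem sizes used by the tests and the acceptance script: 150
patients (≈ 165 visits of 11 min at 4 Hz), 5-fold cross-validation with 5
trials in the test suite and 50 in the acceptance script over a reduced
SVR grid ($C \in 2^{\{-1,1,3,5,7\}}$, $\epsilon \in 2^{\{-8,-6,-5\}}$),
and 100 testing repetitions with `tune_once = TRUE`.

Passing these tests shows the pipeline's *internal* correctness — each
stage recovers planted structure at realistic noise — not field validity.
The generator contains no fetal movement, maternal heartbeat
cross-talk, talking/interference acoustics (beyond labels), gestational
dating error, or inter-site device variation; real cohorts will show
higher errors and weaker discrimination than the synthetic figures.

## Known limitations

* The ratio-rule history uses retained (measured) estimates only; what the
  original pre-processing did when the previous two estimates were
  themselves interpolated is not documented.
* One feature-name ambiguity is resolved as `std_is / rmssd_is` (its
  reciprocal appears under both orientations in the literature this
  follows); either orientation is a monotone transform of the other.
* Whether spectral features should use the FHR trace or the interbeat
  sequence is ambiguous in the source description; the FHR trace is used
  as written.
* The per-repetition rank-sum comparison shares test visits across
  repetitions (pseudo-replication); it measures the stability of the
  NBW/LBW error gap, not population-level significance.
* GA months are modelled as exact labels; real LMP dating error would blur
  the month boundaries and inflate all reported errors.
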