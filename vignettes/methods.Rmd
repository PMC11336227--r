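---
title: "Pre-stimulus oscillations and perceived valence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-stimulus oscillations and perceived valence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`prestim` implements an EEG analysis chain for one scientific question: is
the oscillatory state of the brain in the seconds *before* an ambiguous
emotional face appears predictive of the valence the observer will report,
and does that state carry the observer's negativity bias?  This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The experimental structure being modeled

Each subject completes two sessions: a long session of repeated artificial
faces (210 trials by default) and a short session of unique natural faces
(68 trials).  Every trial yields a rating — negative, positive, neutral, or
missed — and an EEG epoch of −2000…+2000 ms around face onset at 500 Hz
over 60 scalp channels.  All group analyses run on the two valence classes
with per-subject trial counts equalized by random subsampling of the larger
class, and a subject enters group statistics only with at least 10 trials
per class (`inclusion_check()`).

## Time–frequency model

Single-trial power is a sliding-window Hann-tapered DFT
(`tfr_hanning()`): one 500 ms window at all frequencies (2–120 Hz in 1 Hz
steps), moving in 50 ms steps.  Numerical choices:

* **Taper.** The *periodic* Hann window. Its transform has exact nulls on
  the DFT grid, so a unit-amplitude sinusoid at an on-grid frequency yields
  power exactly 1 (amplitude² ), independent of window length — the
  normalization is `2 / Σ h(k)`.
* **Edges.** A window center whose 500 ms support would leave the epoch is
  *undefined* (`NA`), never zero-padded; undefined points are excluded from
  all statistics. The analysis windows used downstream (−1500…−500 ms
  baseline, −500…1500 ms statistics, −1000…−200 ms features) never touch an
  edge on the default grid.
* **dB baseline** (`tfr_db_baseline()`): `10·log10(P / mean P over
  −1500…−500 ms)`, per trial, channel and frequency, applied only on the
  univariate branch. The decoding branch deliberately consumes raw power —
  baselining is a per-trial rescaling that could leak pre-stimulus
  information structure.
* **Frequency grid.** Off-grid frequencies are not interpolated; power
  above 60 Hz is computed but not tested.

## Cluster-based permutation statistics

Point-wise statistics over channels × frequencies × times (paired t for the
valence contrast; Pearson r of the per-subject power difference against the
negativity bias for the covariate design) are corrected with a Monte Carlo
cluster test (`cluster_permutation()`):

* **Null generation.** Paired design: random within-subject condition
  swaps, i.e. sign flips of the per-subject differences (sign flips leave
  each dᵢ² unchanged, so the permuted t is computed in closed form from one
  matrix product). Covariate design: random re-pairing of the covariate.
* **Forming threshold.** Default `nonparametric_individual`: each point's
  own α and 1−α permutation quantiles, computed from the same permutation
  set that is reused for the cluster null (a single-pass approximation; the
  parametric Student-t threshold is also implemented). Degenerate points
  (zero variance, collapsed permutation distributions, epoch-edge `NA`s)
  are excluded from clustering entirely.
* **Connectivity.** Two suprathreshold points of the same sign are
  neighbors if they share a channel edge of the montage graph at the same
  frequency/time, or are adjacent in frequency or in time. The montage is a
  60-channel template layout; channels are neighbors within a distance
  threshold calibrated so the median degree is ≈ 6 (the montage is
  schematic, not digitized — sufficient for neighborhood structure, not for
  source analysis).
* **Inference.** Cluster mass = sum of member statistics ("maxsum"); per
  permutation the maximal positive and maximal |negative| masses are kept;
  `p = (1 + #{null ≥ observed}) / (n_perm + 1)`, so the smallest attainable
  p at 2000 randomizations is 1/2001. Positive and negative tails are
  tested separately, each at α = 0.025.

With 12 subjects and 500 permutations the measured per-tail family-wise
error rate over 200 null replicates is statistically consistent with 0.025
(see `tests/testthat/test-acceptance.R`).

## Decoding

Features are raw power averaged over the pre-stimulus window and flattened
to channel × frequency (2…`fmax` Hz), channel-major.  The feature window
defaults to −1000…−200 ms; `build_features()` additionally drops any window
center whose 500 ms analysis window would cross stimulus onset (effective
centers −1000…−250 ms), which makes the purity guarantee exact: zeroing all
data at t ≥ 0 changes no feature and no accuracy.  The stated −200 ms upper
bound alone would not guarantee this (a −200 ms center's window reaches
+48 ms), and we treat the purity claim as the binding one.

* **Classifier.** Linear SVM (e1071/libsvm), cost C from
  `10^(−2…2)` by default via inner stratified 5-fold accuracy on the
  training set only; ties go to the smallest C; refit on all training data.
  Features are standardized with training-set statistics.
* **Within-subject cross-decoding.** Train on all equalized experiment-1
  trials, test exactly once on all equalized experiment-2 trials (they are
  few and unique; no resampling). Chance is exactly 0.5 by the balance
  guarantee.
* **Accuracy statistics.** One-sided exact binomial
  `P(K ≥ k | n_test, 0.5)`; mask at p ≤ 0.05; *peak accuracy* is the
  maximum within the mask, falling back to the global maximum. Two accuracy
  modes exist because a time-averaged feature set yields a single accuracy
  (mode `"single"`, the default) while the peak/mask semantics presuppose a
  vector; mode `"per_frequency"` trains one decoder per frequency on that
  frequency's channel features and realizes the peak logic non-vacuously.
  Both are labelled in every result.
* **Group level (LOPOCV).** Per subject and experiment, each feature is
  z-transformed across that subject's trials (removing subject-specific
  scale); the SVM trains on the pooled experiment-1 trials of N−1 subjects
  and tests on the held-out subject's experiment-2 trials; every subject is
  tested exactly once. Training data are equalized per subject before
  pooling (consistent with the univariate pipeline); counts are logged.
* **Previous-rating control.** Trials whose previous rating is neutral,
  missed or undefined (first trial) are removed; the rest are subsampled so
  the four (previous, current) label cells are balanced. Control A trains
  on *previous*-trial labels and evaluates those same trials against their
  *current* labels; control B is a stratified 5-fold × 4-repetition decode
  of the current labels; per-subject accuracies are compared by paired t.
  A limitation worth stating plainly: with p ≫ n features a linear SVM
  interpolates its training labels, so control A's accuracy reduces to the
  previous/current label agreement of the tested trials — which the
  balanced selection fixes at exactly ½ whenever all four cells are
  populated. The control therefore guards against label-sequence artifacts
  rather than measuring a previous-label pattern per se; a
  cross-validated variant would be needed for the latter.

## Behavioral statistics

Negativity bias = `100 · n_negative / (n_negative + n_positive +
n_neutral)` — a neutral response is a logged rating and stays in the
denominator; missed trials carry no response and are excluded.  The
between-experiment comparison is a paired t over the subjects usable in
both experiments (the subset rule, not any particular N, is what is
implemented).  Bias is correlated (Pearson) with BDI-2, STAI-S and STAI-T
scores per experiment.

## The synthetic-data generator

`simulate_subject()` builds each trial as the sum of three processes per
channel:

1. **1/f^β background** (`pink_noise()`), spectral synthesis with exact
   unit variance, β = 1 by default, scaled to 10 µV;
2. **ongoing alpha**: a 10 Hz sinusoid, 3 µV, random phase per trial and
   channel;
3. **the effect carrier**: a Hann-enveloped burst (`oscillatory_burst()`)
   at a frequency drawn uniformly from the effect band (8–12 Hz) in the
   effect window (−500…0 ms) at the effect channels (CP3, CP5, C3 — left
   centro-parietal, where the alpha contrast is expected), at 25 µV base
   amplitude on positive-rated trials and `25 · 10^(db/20)` µV on
   negative-rated trials.

The effect is an *amplitude modulation of an always-present burst*, not an
additive evoked response, because the tested quantity is induced band power
in dB.  The 25 µV base amplitude was chosen so the burst dominates band
power at the effect channels and the realized dB contrast tracks
`effect_size_db` (measured: 2.87 dB realized for 3 dB requested; at 15 µV
the background diluted the contrast to ≈ 2.5 dB).  A 1 dB contrast yields a
single-trial alpha-band effect size of d ≈ 1 at CP3/CP5 — the regime used
for the decoding calibration checks.  Ratings are i.i.d. per trial with a
per-subject negative-rating probability drawn as experiment mean (0.55 /
0.65) plus a shared subject offset ~ N(0, 0.12), truncated to [0.05, 0.95]
— the between-subject spread that the bias-correlation analysis requires —
and `bias_effect_slope_db` optionally couples a subject's effect size to
that offset.  Post-stimulus effects can be injected through `post_effect`
but are off by default: the pre-stimulus claims are the surface under test.
Missed responses default to probability 0 (the pipeline excludes them
upstream anyway).

What the generator does **not** emulate: volume conduction and realistic
source topographies (no forward model), eye/muscle artifacts, evoked
potentials, autocorrelated rating sequences, non-stationary drift.
Passing tests therefore demonstrate that the *analysis machinery* is
correct and calibrated on data with the assumed statistical structure —
they do not certify performance on real recordings with artifacts and
richer covariance.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run on reduced cohorts chosen as
the smallest sizes at which each property is statistically decisive: 8–16
channel sub-montages around the effect sites, 2–30 or 2–40 Hz grids, 200
null replicates at 500 permutations for the family-wise error calibration,
12–50 simulated subjects for the decoding calibrations, and the study's own
session sizes (≈120 usable experiment-1 trials, 68 experiment-2 trials)
where training-set size matters.  The acceptance script's cohort (12
subjects, 16 channels, 2–40 Hz, 1000 permutations) reports bias means,
cluster p-values, and decoding statistics computed exactly as the
full-scale pipeline would.

## Known limitations

* The montage is a schematic template; do not use it for topographic
  inference beyond neighborhood structure.
* Nonparametric-individual forming thresholds reuse the cluster-null
  permutation set (single pass); this is the standard approximation and is
  covered by the family-wise error calibration test.
* Manual artifact rejection and ICA cleaning of real recordings are
  interactive, visual procedures with no faithful automatic surrogate; the
  import layer (BrainVision/EDF) assumes already-clean continuous data.
* The same-trial previous-rating control is agreement-bound in the
  interpolating regime (see above).
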