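---
title: "Quantitative EEG dysmaturity and neurodevelopmental outcome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG dysmaturity and neurodevelopmental outcome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Infants with tuberous sclerosis complex (TSC) carry a high risk of
autism spectrum disorder (ASD) and developmental delay, and an EEG is
usually recorded within weeks of birth. A neonatal EEG background that is
*dysmature* — inappropriate for the infant's gestational age — shows
excessive discontinuity (long, deeply suppressed interburst intervals),
persistence of very slow delta activity (< 2 Hz at term age), and
interhemispheric asynchrony of burst onsets. `tscqeeg` implements a
complete, seeded analysis of the question: does early background
dysmaturity predict 24-month neurodevelopmental outcome?

Because no individual-level recordings are distributed with the package,
every stage runs on synthetic data whose generating parameters are
explicit, and the statistical machinery reproduces the published 2x2
association figures exactly from their printed counts.

## Synthetic neonatal EEG

`generate_eeg()` models the background as a two-state renewal process:
the trace alternates between *bursts* and *interburst intervals*, with
gamma-distributed durations (the gamma family keeps durations positive
and lets one dispersion knob, `ibi_cv`, control regularity; the shape
parameter is `1 / ibi_cv^2`). Within each state the signal is Gaussian
noise with a two-component spectrum — a very-slow band (0.5–2 Hz) and a
faster band (2–30 Hz), each mildly `1/f`-weighted — mixed so that
`slow_delta_frac` of the power lies below 2 Hz. A raised-cosine ramp of
about 0.25 s smooths state transitions. Homologous left/right channels
share burst timing; with probability `asynchrony_prob` a burst reaches
the contralateral hemisphere only after `asynchrony_lag_ms`. Midline
channels follow the left-hemisphere clock.

The two reference profiles are documented configuration defaults, not
clinical claims (age-specific interburst-interval norms are deliberately
not modelled):

| parameter | mature | dysmature | unit |
|---|---|---|---|
| `ibi_mean_s` | 3 | 8 | s |
| `burst_mean_s` | 2 | 2 | s |
| `burst_amp_uv` | 50 | 50 | µV RMS |
| `interburst_amp_uv` | 25 | 10 | µV RMS |
| `slow_delta_frac` | 0.4 | 0.7 | — |
| `asynchrony_prob` | 0.05 | 0.4 | — |

A profile flagged `dysmature` must be component-wise at least as immature
as the mature defaults on `ibi_mean_s`, `slow_delta_frac` and
`asynchrony_prob`, so labels can never contradict parameters.

What the generator does **not** emulate: sleep-stage architecture (the
discontinuity and asynchrony knobs are the only carriers of immaturity),
interictal epileptiform discharges, seizures, artefacts, and volume
conduction between channels (channel noise is independent given the
burst envelope). Consequently, a passing direction-of-effect test shows
that the *feature estimators* respond correctly to discontinuity,
slow-delta persistence and asynchrony — it does not validate them
against real neonatal recordings.

`generate_cohort()` draws per-subject records: dysmaturity is
Bernoulli(`p_dysmature`), 24-month ASD status follows the conditional
probabilities of the risk design, ADOS-2 scores are drawn consistently
with the risk category and verbal status, and developmental quotients
(DQs) are truncated-normal draws whose mean drops under dysmaturity
(80 vs 65, SD 15 — centred near the mid-70s cohort medians). The default
design encodes the study conditions: 64 infants, `p_dysmature = 14/63`,
ASD risk `8/14` given a dysmature EEG vs `11/49` given a mature one
(odds ratio 4.6), TSC2 in 72%, preventive treatment in 30%, and exactly
one infant with missing follow-up. The other visual flags (IED, focal
slowing, seizures) are drawn independently of the outcome, so in
simulations the composite "abnormal EEG" exposure is a diluted version
of the dysmaturity effect — only dysmaturity carries the designed link.

## The four feature families

1. **Relative band power** (`band_power()`): Welch PSD (4-s Hann
   segments, 50% overlap), integrated over δ1 = 0.5–2, δ2 = 2–4,
   θ = 4–8, α = 8–16, β = 16–30 Hz and normalised to sum to 1 per
   channel. The δ1 upper edge of 2 Hz isolates the "extremely slow
   delta" band that defines dysmaturity at term age; all edges are
   configurable because no standard fixes them for neonates.
2. **Range-EEG asymmetry** (`range_eeg()`): the signal is cut into 2-s
   non-overlapping epochs; each epoch contributes its peak-to-peak
   amplitude (µV). With median M and margins L/U (5th/95th
   percentiles), the asymmetry is `A = ((U−M) − (M−L)) / (U−L)`,
   normalised to [−1, 1]. A discontinuous trace — sparse high-amplitude
   bursts over a suppressed background — skews the epoch distribution
   right and drives A positive. A constant trace has `U = L` and A is
   reported as undefined, never 0.
3. **Multiscale sample entropy** (`multiscale_entropy()`):
   SampEn(m = 2, r = 0.2·SD, Chebyshev distance, self-matches excluded,
   n − m templates at both lengths) on coarse-grained series at scales
   1..20. By default the tolerance is re-anchored to each scale's SD
   (`r_mode = "rescaled"`); the classical fixed-tolerance convention is
   available as `r_mode = "fixed"`. The two differ for white noise —
   the fixed-r curve decays with scale while the rescaled curve stays
   flat, because iid noise is again iid after coarse-graining — but both
   flag the loss of long-time-scale complexity in correlated signals.
   Zero template matches yield an explicit undefined value, never a
   silent infinity. The O(n²) template counting is compiled (Rcpp).
4. **Hurst exponent** (`hurst_exponent()`): first-order detrended
   fluctuation analysis — 12 logarithmically spaced window sizes in
   [4, n/4], per-window linear detrending of the cumulative profile,
   H = slope of log F(n) vs log n. DFA was chosen over rescaled-range
   analysis for robustness to nonstationarity; H > 1 is allowed. The
   estimator recovers H = 0.5 on white noise and H = 0.8 on fractional
   Gaussian noise synthesised by circulant embedding (`sim_fgn()`),
   which serves as simulated ground truth in the tests.

Preprocessing is a zero-phase 0.5–30 Hz band-pass plus amplitude-clipping
detection (2-s epochs exceeding 500 µV are counted, not removed);
component-based artefact rejection is a human step outside scope.
Features are computed per channel over the whole record (no sleep-state
segmentation) and aggregated across channels by the median for
classification.

## Classification

`three_fold_evaluate()` reads "three-fold testing" as stratified 3-fold
cross-validation: two thirds train, one third test, each subject held
out exactly once, per-fold class counts differing by at most one. Inside
each training fold the most discriminant features are selected by the
Fisher criterion (absolute standardised mean difference, k = 5 by
default, ties to the lower index) — selection inside the fold is what
the leakage canary test guards. The classifier is two-class LDA from
first principles: `w = Σ_pooled⁻¹(μ₁ − μ₀)`, threshold at posterior
odds 1 under the empirical priors, ridge term `λ·tr(Σ)/p` only when the
pooled covariance is singular (messaged and flagged). Performance is
reported as misclassification error E(%) and AUC(%), AUC via the
Mann-Whitney identity with midranks (ties count ½), pooled over the
held-out predictions by default (per-fold averaging is a flag, as is a
repetition count for repeated partitions). Published real-cohort AUC
values are *not* reproduction targets — the recordings are unavailable —
so the classifier is validated by properties instead: perfect
performance on separable features, chance-level AUC under label
permutation, and above-chance detection of the synthetic dysmaturity
signal.

## Outcome statistics

* ADOS-2 risk bands: non-verbal 0–9 / 10–13 / >13, verbal 0–7 / 8–11 /
  >11 (no risk / mild-moderate / high). The binary "ASD symptoms"
  outcome is the any-risk dichotomy, which matches the reported 19/63 =
  30% prevalence; the three-level category is kept in the data model.
* 2x2 analysis: OR = ad/bc with Wald 95% CI; the Haldane–Anscombe +0.5
  correction is applied to all cells only when a cell is zero (and
  flagged). Sensitivity, specificity, PPV and NPV are undefined (NA)
  when their denominator is zero. Reported percentages round half-up to
  integers and ORs to one decimal, matching print conventions.
* Logistic regression wraps the IRLS fit of `stats::glm` (tolerance
  1e−12, 50 iterations) and adds the clinical reporting layer: Wald
  standard errors and p-values, OR with 95% CI, likelihood-ratio omnibus
  chi-square and Nagelkerke R². Perfect separation raises an error
  naming the predictor; an all-one/all-zero outcome returns a flagged,
  unconverged result. Multivariable models enter all covariates in one
  block.
* Mann-Whitney tests use exact enumeration when n₁+n₂ ≤ 12 without
  ties, otherwise the tie-corrected normal approximation with continuity
  correction. Exhaustive enumeration shows that approximation to be
  within 0.015 of the exact p everywhere it is used (n₁, n₂ ≤ 8,
  n₁+n₂ > 12) and within 0.01 for the large majority of outcomes.
* DQ models: DQs must be positive; the cognitive and language quotients
  are log-transformed and the motor quotient reciprocal-transformed
  before OLS (the split between the two transforms is a package choice —
  the source analyses used both without fixing the mapping), with
  inverse transforms provided for reporting. Collinearity is screened by
  VIF/tolerance from auxiliary regressions (flagging VIF = ∞ under
  perfect collinearity).

## Problem sizes and reproducibility

Every randomised operation takes an explicit seed and restores the
caller's RNG state (`with_seed()`); identical inputs give bit-identical
output, including the end-to-end `run_pipeline()` JSON summary. The test
suite and `scripts/acceptance.R` use: 100 random series (n ≤ 300) for
the sample-entropy oracle battery; 50 seeds of n = 8192 for each DFA
recovery check; 40 + 40 recordings (120 s, 64 Hz, C3/C4) for the
direction-of-effect suite (20 + 20 in the acceptance script); 200 label
permutations for the classifier null; and 500 simulated cohorts of
n = 63 for odds-ratio recovery, where the median estimated OR and the
Wald-CI coverage of the design value 4.6 are checked. The analysis
scripts under `analysis/` run the same machinery at the full study size
(64 subjects, 9 channels).

## Known limitations

* The generator's profiles are working defaults; thresholds that would
  map gestational age to expected interburst durations are not encoded.
* Only dysmaturity is linked to outcome in the simulation; associations
  for composite or other EEG exposures are attenuated by design.
* Adjusted (multivariable) odds ratios from the source cohort are not
  reproducible without individual-level covariate data, and are not
  targets; the model machinery is nonetheless exercised end to end.
* Features are whole-record; quiet-sleep-specific analysis would need
  the sleep staging the generator deliberately lacks.
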