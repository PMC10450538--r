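---
title: "Case-only analysis of surge-by-characteristic interactions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only analysis of surge-by-characteristic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and what the design buys

`surgecase` estimates effect modification between a population-level,
time-varying binary exposure (a "surge day" in a daily count series of
suicide-related posts) and individual characteristics of death records,
using only the cases. The generating model for the daily death count in
characteristic stratum $j$ is Poisson:

$$\log E[Y_{tj}] = \beta_0 + \beta_1 \,\mathrm{Surge}_t + \beta_2 C_j +
\beta_3\, \mathrm{Surge}_t\, C_j + \mathrm{Others}_t$$

The quantity of interest is $e^{\beta_3}$, the multiplicative interaction.
Among cases, the expected 2×J table of deaths by surge status and
characteristic level has cross-product ratios equal to $e^{\beta_3}$
exactly, because every term shared across strata — including the whole
$\mathrm{Others}_t$ nuisance (seasonality, weekday structure, news cycles)
— cancels from the ratio. The estimator is therefore the cross-product
ratio of the observed case table, equivalently the exposure coefficient of
a (multinomial) logistic regression of the characteristic on surge status
among cases. Its one substantive assumption is that characteristic and
exposure are independent in the base population; no covariates are used.
The package tests this cancellation directly: doubling the shared seasonal
amplitude in the generator moves the mean case-only estimate by well under
0.02 on the log scale (see `tests/testthat/test-acceptance.R`).

## Surge detection

* **Previous-day ratio.** Exposure is defined on the day-to-day increase
  ratio $x_t / x_{t-1}$, not the level, so slow drifts in platform usage do
  not masquerade as surges. Day one and any day following a zero count have
  an *undefined* ratio: they are excluded from threshold computation, their
  exposure is undefined, and records mapping to them are dropped and
  counted in the run log. No imputation is defensible there.
* **Threshold.** A day is exposed when its ratio is *at or above* the 95th
  percentile of all defined ratios. The percentile is nearest-rank: the
  smallest observed value with at least 95% of observations at or below it,
  i.e. rank $\lceil 0.95\,n \rceil$ of the sorted ratios. This rule is
  deterministic, tie-safe (a fully tied series is all-exposed, since "at or
  above" is inclusive), invariant to strictly increasing transforms of the
  ratios, and gives the exact flagged-day count $n - \lceil 0.95 n\rceil +
  1$ on distinct ratios. The rank computation guards against upward
  floating-point error in $0.95 \times n$ with a $10^{-9}$ tolerance so
  that exact ranks stay exact.
* **Denoising.** Daily post counts carry multiplicative external noise
  (user-base growth, platform outages). The package detrends by dividing
  each count by a centered moving median (window truncated at the series
  edges) and rescaling by the global median to stay on the count scale;
  `window_days = 0` disables it, and an externally denoised column supplied
  through `tweet_series()` is used as-is. The moving-median choice is the
  package's own: it is robust to the very spikes the classifier must
  preserve, and a 7-day default window removes weekday structure. Users
  with a preferred noise-elimination method should supply its output
  directly.

## Cohort handling

* **Cause ranges.** Suicide is ICD-10 X60–X84; the sensitivity mode uses
  other external-cause deaths in W00–X59 and Y01–Y59. Note that this
  sensitivity set deliberately omits X85–Y00 (assault and related codes);
  the two modes are disjoint by construction. Range membership compares the
  3-character prefix only — a 4th character is ignored.
* **Exclusions.** Records with missing age, missing occupation, or marital
  status "other" are excluded. Drop counts are assigned to reasons in that
  fixed order (mutually exclusively) so the accounting identity `records in
  = records kept + sum of drops` holds exactly and is asserted on every
  run.
* **Recoding.** Age is binarized at 40 or younger ("young") vs older — the
  group assumed most exposed to the platform. Occupation uses
  "self-employed" and marital status "married" as base levels.
* **Lagged merge.** A record dying on day $d$ receives the exposure of day
  $d - \ell$ for each configured lag $\ell$ (defaults 3 and 7 days, lags a
  few days longer than the 0–2 days used for meteorological exposures,
  since a media effect is less biologically direct). The lag is a point
  lookup, not a "any surge in the last $\ell$ days" window: the single-lag
  formulation is the one whose interaction coefficient the case-only table
  identifies. Records whose lagged date falls outside the calendar or on
  an undefined-exposure day are dropped and logged.

## Estimation

Closed forms are the primary path: the binary case-only OR
$(n_{11}n_{00})/(n_{10}n_{01})$ with Wald SE
$\sqrt{\sum 1/n_{ej}}$, and per-level RRRs against the base column with the
analogous four-cell SE. CIs are Wald on the log scale at 95%
($z = 1.959964$); profile-likelihood intervals are out of scope. The
`significant` flag is a two-sided Wald $p < .05$ with **no
multiple-testing adjustment**, matching common practice in this design;
treat it accordingly when scanning many levels and lags.

Two independent routes verify the closed forms on every call:

* a maximum-likelihood logistic fit (IRLS via `glm` on the weighted cells)
  for binary tables, and a Newton–Raphson baseline-category multinomial
  logit MLE for multi-level tables, each required to agree with the closed
  form to $10^{-6}$ relative. Newton iteration is used for the multinomial
  fit because the saturated MLE must be reproduced to near machine
  precision for the identity check to be meaningful at large counts;
  quasi-Newton optimizers plateau around $10^{-6}$–$10^{-5}$ on unbalanced
  tables. The test suite additionally cross-checks the Newton fit against
  `nnet::multinom` at that fitter's achievable tolerance.
* a saturated Poisson log-linear model (`count ~ exposure * level`) on the
  four cell totals — the count-model formulation — whose interaction
  coefficient must equal the case-only log OR (saturated-model identity).

**Zero cells fail loudly.** Surge days are rare (~5% of days), so small
strata can produce empty exposed cells. By default this is an error; an
explicit `correct = TRUE` adds 0.5 to every cell and tags the estimate
`closed_form_corrected` (the ML check is skipped there, as the corrected
table no longer corresponds to integer data). Silent correction would bias
small tables invisibly. Cell counts are promoted to doubles before
cross-products, which would otherwise overflow 32-bit integers near
$10^5$ per cell.

## The synthetic-data generator

The study's mortality data (restricted vital statistics) and tweet data
(commercial sample) are not available, so the generator is a first-class
module that emulates their structure with known ground truth:

* **Scale.** Defaults mirror the 2011–2014 study span: 1461 days, expected
  totals of ~159,490 suicide and ~115,072 other unexpected deaths
  ($e^{\beta_0}$ parameterized as the expected *total* daily count), and
  ~1,920 daily posts (2.8M over the span).
* **Tweet process.** Counts are baseline × lognormal noise (SD 0.15 on the
  log scale) × a spike multiplier (uniform 3–6) on injected spike days
  (probability 0.02/day). Injected spike dates are returned as ground truth
  for recall checks (recall ≥ 0.9 is an acceptance property).
* **Death process.** Per day × joint stratum Poisson counts, exploded to
  individual records. Level proportions enter as a log-population offset,
  so $\beta_2$ stays a pure rate ratio; multiple characteristics combine
  independently (proportions multiply, coefficients add). The shared
  $\mathrm{Others}_t$ term is a single sinusoid (amplitude 0.2 on the log
  scale, period one year) plus seven weekday offsets — deliberately the
  *minimal* structure needed to test confounding immunity; the amplitude
  is a configurable package choice, as no empirical magnitude is
  available. Default interaction magnitudes (1.09 young, 1.12 male, 1.12
  unemployed, 0.83 widowed, 1.11 divorced, 1.26 urban) are of the order
  reported for media-linked suicide effect modification, giving realistic
  signal-to-noise for recovery tests.
* **Lag semantics.** The generator applies the surge effect at
  `exposure_lag` days after the surge day (default 3, the primary analysis
  lag), so an analysis at the generating lag recovers $\beta_3$; analyses
  at other lags estimate approximately null interactions because spike
  days are temporally independent. Exposure is undefined for the first
  days of the span and treated as unexposed in generation (affects at most
  `exposure_lag + 1` days).
* **Sensitivity stream.** When enabled, a parallel stream of non-suicide
  external-cause records is drawn from the same model with every $\beta_3
  = 0$ — the negative control the sensitivity analysis should find null.
* **Reproducibility.** One master seed derives independent substreams for
  the tweet and death processes, so toggling one never perturbs the other;
  identical scenario + seed gives identical output, byte for byte.
* **What it does not emulate.** Realistic joint demographic distributions
  (characteristics are independent by construction), tweet text or
  retweet dynamics, autocorrelated surge episodes, or exposure-dependent
  data quality. Passing recovery tests therefore demonstrates correctness
  of the estimator and pipeline under the stated model, not robustness to
  violations of the base-population independence assumption — which no
  case-only analysis can check internally.

## Verification problem sizes

The acceptance properties run at study scale: 1461-day spans with ~150–250k
records per replicate; 200 replicates for recovery bias (<0.01 on the log
scale) and CI coverage (92–98%), 500 for type-I error (3–7% at
$\alpha=.05$), 200 paired replicates for seasonal-confounding immunity
(<0.02 shift), 100 for the null sensitivity stream (mean log estimates
within ±0.02) and end-to-end coverage (≥93% pooled), plus 1,000 random
tables for the closed-form/ML and Poisson-oracle identities at $10^{-6}$.
`scripts/acceptance.R` recomputes the same quantities with moderately
smaller replicate counts (its JSON records the `n` used for each).

## Known limitations

* The Wald CI and SE come from the asymptotic four-cell formula; very
  sparse tables need the explicit continuity-correction mode and its
  estimates should be read cautiously.
* The previous-day-ratio definition makes the day after a surge look like
  a trough; consecutive-day spike episodes are partially self-masking
  (the second day's ratio is near 1). Spike recall is high only when
  surges are mostly isolated days, as in the generator.
* The sensitivity cause set omits X85–Y00 by specification; users wanting
  the full non-suicide external-cause complement can pass their own ranges
  through `icd10_in_range()`/`select_cause()` building blocks.
* Significance flags are unadjusted for multiplicity across levels and
  lags.
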