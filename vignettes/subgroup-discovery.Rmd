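---
title: "Subgroup discovery for social support and mental distress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgroup discovery for social support and mental distress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmcohort)
```

## The scientific question

Low social support is an established risk factor for depression, anxiety
and stress in older adults, but the strength of the association is not
uniform: it plausibly differs by gender, age, education and marital
status, and by their interactions. `palmcohort` implements the
exploratory machinery for finding such subgroups: model-based recursive
partitioning (MOB) with a linear node model, and its partially additive
variant (PALM trees) in which a designated set of covariates keeps
global, subgroup-invariant coefficients.

The exposure is the SSQN number score of a 4-item short form of the
Social Support Questionnaire: each item counts how many of six types of
social contact a participant can rely on (0–6); the item mean is the
phase score, and the mean over five survey phases spanning two decades
is the aggregate SSQN. The outcomes are the DASS-21 subscales
(depression, anxiety, stress; doubled 7-item sums on the 0–42 scale) and
a general-distress composite, analysed as z-scores. Effects are
reported per unit *decrease* in SSQN, so positive slopes mean more
distress with less support.

Because the emulated cohort's data are access-restricted, the package
ships a calibrated synthetic generator that reproduces the cohort's
published descriptive structure and plants known subgroup effects, so
that every stage of the pipeline is testable end to end.

## The MOB node cycle

In each node the linear model `y = a + b x + e` is fitted by OLS. The
per-observation estimating functions `psi_i = (r_i, r_i x_i)` (residual
and residual times regressor) sum to zero at the estimate; parameter
instability along a candidate modifier means these scores fluctuate
systematically when grouped or ordered by it.

* **Categorical modifiers.** With level sums `S_c` and the outer-product
  covariance estimate `Vhat = crossprod(psi)/n`, the statistic
  `T = sum_c S_c' Vhat^{-1} S_c / n_c` is asymptotically chi-square with
  `2 (C - 1)` degrees of freedom under stability. All four modifiers in
  the cohort analysis are categorical.
* **Ordered/numeric modifiers.** The decorrelated cumulative score
  process is evaluated at the observed split fractions inside a trimmed
  band (`trim = 0.1`), and the supLM functional
  `max ||W(t)||^2 / (t(1-t))` is compared against a seeded Monte-Carlo
  sample of discretized Brownian bridges on the same grid (`n_mc`
  replicates, default 10,000). A Monte-Carlo reference was preferred
  over tabulated asymptotic approximations: it has no magic constants
  and its error is controlled by `n_mc`.

Variable selection applies a Bonferroni correction over the `m` tested
modifiers (`p_adj = min(1, m p_raw)`), picks the smallest adjusted
p-value (ties: larger statistic, then smaller index), and splits only if
`p_adj <= alpha`. The split itself is found by exhaustive search — all
`2^(C-1) - 1` binary level partitions, or all midpoints between distinct
values — minimising the summed child RSS subject to a minimum child size
(`minsize = 20`). Recursion stops at `maxdepth` (root = depth 1; the
cohort analysis uses `maxdepth = 3`, at most four leaves), when a node
is too small, or when no significant instability remains.

With the exploratory setting `alpha = 1` every admissible node splits,
so reported split p-values are descriptive, not confirmatory; tree size
is governed by the depth cap alone. Both raw and adjusted p-values are
recorded per node; displays default to the adjusted one.

## PALM trees: global additive effects

`fit_palm()` alternates (i) adjusting the response for the current
global effects `y - G gamma`, (ii) growing a MOB tree on the adjusted
response, and (iii) a joint OLS of the raw response on leaf-wise
intercepts and slopes plus the dummy-coded globals. Convergence is
declared on the relative change of the joint RSS (`tol = 1e-8`) or the
maximum coefficient change (`1e-6`); the trace is retained and is
non-increasing after the first iteration.

The partitioning variables and the global covariates are the same four
sociodemographics. Global dummy columns that the leaf structure spans
(e.g. the gender dummy once the tree splits on gender) are dropped from
the global block with a warning and absorbed into the leaf intercepts;
this is the expected behaviour when a variable is both adjusted for and
split on. Leaf slopes get Wald intervals with normal quantiles from the
final joint fit — at cohort size the difference from t quantiles is
below the reporting resolution. The confidence intervals inherit the
usual post-model-selection caveat: the tree was chosen on the same data,
so nominal coverage is approximate.

`subgroup_slope()` reports the estimate for a *named* demographic
subgroup: the leaf estimate itself when a leaf coincides with the
subgroup, otherwise the membership-weighted average of leaf slopes over
the subgroup's members.

## The synthetic cohort generator

The generator is the package's definition of the study conditions; its
defaults were calibrated once and frozen.

* **Demographics.** Exact configured marginals (women 3,627 / men 839;
  ages 60–72 2,477 / 73–82 1,989 of n = 4,466), assigned by independent
  permutations, so attributes are mutually independent. Marital and
  education marginals are the published observed counts rescaled to the
  full sample, because 2% and 1% of those responses are masked later.
  The published joint distribution is unknown; independence is an
  explicit simplification. 57 extra participants with entirely empty
  DASS-21 questionnaires are generated beyond the 4,466 so the inclusion
  filter is exercised without disturbing the exact marginals.
* **SSQ items.** A one-factor ordinal model: participant trait shared
  across phases (correlation 0.6), item latent value = 0.87 × phase
  trait + residual, discretized through six calibrated thresholds into
  counts 0–6. Calibration targets: SSQN median 1.50, IQR near
  (1.15, 2.05), Cronbach's alpha 0.90. The realized IQR is (1.05, 2.00)
  — slightly wide at the low end — and the median sits on the 0.05
  lattice of 20-item means, so seeds land on 1.50 or 1.55.
* **DASS items.** Per subscale, latent z = subgroup intercept + planted
  slope × (mean SSQN − SSQN) + global shifts + Gaussian noise (half the
  noise variance shared across subscales as a common distress
  component). z maps to a raw doubled score through calibrated norm
  means/SDs, rounded to the nearest even integer and clipped to
  [0, 42]; the raw score is allocated uniformly over admissible 7-item
  vectors via a composition-count table. The planted slopes are the
  published subgroup estimates; intercepts are the free calibration
  knobs that realize the published split structure (gender gaps of
  opposite sign for depression and stress so they cancel in the
  composite; anxiety carries the age gap; education gaps reinforce).
* **Slope correction.** Clipping at zero shrinks both the raw-scale
  slope and the raw-scale SD. The generator divides each latent slope by
  the closed-form recovery factor (average clip derivative over the
  subgroup divided by the mixture SD ratio), so the planted value is
  what OLS on the *scored* data recovers. With rounding disabled
  (`round_items = FALSE`) no correction is applied and the latent plant
  is recovered exactly — the basis of the exact plant-recovery tests.
* **Missingness.** Whole SSQ phase blocks are masked at age-dependent
  rates (4.8% / 6.4% per phase, missing at random: the probability
  depends on observed demographics only), giving ~24.7% of participants
  any missing support response; education and marital status at 1% and
  2%; 296 participants lose a random nonempty proper subset of DASS
  items; the 57 designated participants lose all 21.

What the generator does *not* emulate: phase-specific attrition, the
real joint demographic distribution, the bifactor measurement structure
of the DASS-21, and the full skew of the raw subscale distributions (a
Gaussian latent scale cannot reproduce a median of 4 with a mean of 6.4
under the observed zero-share; the calibration prioritises the
general-distress median and mean, the depression zero-share and the
psychometrics). Passing tests therefore certify the *procedure* under a
faithful but simplified data model, not the published data themselves.

The general-distress composite (the mean of the three doubled subscales
— a documented approximation of the bifactor general factor, whose
validation is out of scope) inherits its structure from the three
subscale plants; its education-first split emerges rather than being
planted. The emergent education partition is {low} vs {medium, high}
rather than the published {low, medium} vs {high}: the depression
plant's own within-gender education split (low vs medium+high)
necessarily imprints that shape. The first-split *variable* matches.

## Imputation

`impute_chained()` is chained-equations imputation tailored to the
cohort tables: education and marital status by multinomial-probability
draws from a fitted log-linear model; SSQ and DASS items by predictive
mean matching (5 donors, type-0 matching on fitted values), which keeps
imputed values in their admissible ranges by construction. The visit
sequence is demographics → SSQ items in phase order → DASS items
(predictors before outcomes), for 10 passes by default. Phase-varying
SSQ items use the participant's mean over their other originally
observed SSQ cells as a predictor — a two-stage surrogate for a
random-intercept repeated-measures model, documented as an
approximation. Items are imputed at item level (the published analysis
imputed partial DASS responders before scoring); whether the original
analysis imputed at item or phase-score level is not stated, so this is
configurable upstream of scoring. `m > 1` completed datasets are
supported, with estimates averaged and variances pooled by Rubin's
rules when the tree structure agrees; the headline pipeline uses
`m = 1`.

## Numerical choices and degenerate inputs

Quantiles use linear interpolation (R type 7). Rounding to the nearest
even integer is `2 * floor(x/2 + 0.5)` (half-up, deterministic).
Cronbach's alpha uses the unbiased (n−1) variance throughout. An exact
node fit (all scores zero) yields instability statistic 0 and p-value 1
rather than a singular-matrix error; a singular score covariance marks
the node unsplittable on that variable. Constant regressors, empty
leaves and rank-deficient joint designs raise errors; collinearity of
globals with the leaf structure is handled by documented column
dropping. All randomness is seed-controlled: the generator from the
scenario seed, imputation from the plan seed, Monte-Carlo p-values from
the control seed plus the node id.

## Problem sizes used by the test-suite studies

The full-size analyses (n = 4,466) run once each; replication studies
run at reduced scale chosen to keep the suite fast while leaving the
assertions meaningful: the first-split structure study uses 10 seeds at
n = 2,500 with 4 imputation passes; planted-slope recovery after
imputation uses 10 seeds at n = 1,500; CI coverage uses 40 seeds at
n = 1,200; global-effect recovery uses 20 seeds at n = 1,500 on
unrounded scores; the null-size simulations use 2,000 replicates
(categorical, n = 500) and 600 replicates (supLM, n = 250, 600
Monte-Carlo bridges). Binomial slack at these replicate counts is
stated next to each assertion.

## Known limitations

* The confidence intervals are post-selection; the package reports them
  as the original analysis does, with the same caveat.
* `alpha = 1` makes second-level splits on weakly heterogeneous outcomes
  (notably the general-distress composite below the root) partly
  noise-driven; only the primary modifier is a stable feature there.
* The estimate for a named subgroup that the tree does not isolate as a
  single leaf is a membership-weighted summary, not a refitted model.
* The generator's Gaussian latent scale understates the skew of raw
  subscale scores; subscale-level means are not calibration targets.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(seed = 1)
res <- run_analysis(cfg, outcomes = c("general", "depression"))
res$table
autoplot(res$fits$depression)
subgroup_slope(res$fits$depression,
               res$scored[c("gender", "age_group", "education", "marital")],
               gender = "women", education = c("medium", "high"))
```
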