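# palmcohort

Subgroup discovery for the association between low social support and
mental distress in old-age retirees, using model-based recursive
partitioning (MOB) and partially additive linear model (PALM) trees.

## The problem

Low social support predicts depression, anxiety and stress in older
adults, but not equally for everyone: the strength of the association
may differ by gender, age, education and marital status, and by their
interactions. Specifying all candidate interaction terms a priori is
impractical and multiplies comparisons; `palmcohort` instead discovers
subgroups algorithmically. It is written for epidemiologists and
biostatisticians who want a fully scriptable, testable version of this
analysis — including a calibrated synthetic cohort generator, because
the motivating cohort's individual-level data are access-restricted.

## The method

Each tree node fits the linear model

```
z_distress = a + b * (-(SSQN - mean(SSQN))) + e
```

where SSQN is the Social Support Questionnaire number score (mean
contact count of 4 items, averaged over five survey phases) and
`z_distress` is a z-standardized DASS-21 dimension (depression, anxiety,
stress, or the general-distress composite). The sign convention makes
`b` the z-score change per unit *decrease* in support. Each candidate
effect modifier is tested for parameter instability with score-based
fluctuation tests (a chi-square statistic `sum_c S_c' Vhat^-1 S_c / n_c`
over the levels of a categorical modifier; a Monte-Carlo supLM statistic
for ordered ones), p-values are Bonferroni-adjusted across modifiers,
the most unstable variable is split by exhaustive RSS search, and the
cycle recurses (`alpha = 1`, `maxdepth = 3` in the cohort analysis, so
tree size is capped by depth). PALM trees add global covariate effects
`G * gamma` shared across all subgroups, estimated by alternating tree
growing with a joint OLS. Leaf slopes are reported with 95% Wald
intervals, as in the subgroup tables of the motivating study.

The synthetic generator reproduces the cohort's published structure:
exact demographic marginals (3,627 women / 839 men; 2,477 aged 60–72 of
n = 4,466), a one-factor ordinal model for the SSQ items (Cronbach's
alpha 0.90, SSQN median 1.50), DASS-21 items induced by planted
subgroup-specific slopes with realistic zero-shares and medians, and a
missing-at-random mechanism (24.7% of participants with any missing
support response; 57 empty and 296 partial DASS questionnaires).
Chained-equations imputation with predictive mean matching completes the
data before scoring and tree fitting.

## Worked example

```r
library(palmcohort)

cfg <- scenario_config(seed = 1)              # the default study conditions
res <- run_analysis(cfg, outcomes = c("general", "depression"))
report_table_all(res)[c("outcome", "subgroup", "n", "estimate_fmt", "ci")]
```

```
  outcome    subgroup                                            n estimate_fmt ci
1 general    education in {low} & marital in {married}        1011 0.29         (0.20, 0.37)
2 general    education in {low} & marital in {divorced, ...}   746 0.07         (-0.02, 0.17)
3 general    education in {medium, high} & education in {...} 1379 0.15         (0.08, 0.23)
4 general    education in {medium, high} & education in {...} 1330 0.24         (0.17, 0.32)
5 depression gender in {women} & education in {low}           1430 0.18         (0.11, 0.26)
6 depression gender in {women} & education in {medium, high}  2197 0.23         (0.17, 0.29)
7 depression gender in {men} & education in {low}              327 0.13         (-0.00, 0.27)
8 depression gender in {men} & education in {medium, high}     512 0.11         (-0.01, 0.22)
```

Each row is one tree leaf: a subgroup defined by the splits from the
root, its size, and the estimated z-score change in that DASS-21
dimension per unit decrease in the support score with its 95% interval.
Here the depression tree splits on gender first and education second:
women with medium/high education show the strongest association (0.23),
men with medium/high education the weakest (0.11) — the planted
heterogeneity pattern. The general-distress tree selects education as
its primary effect modifier. `subgroup_slope()` extracts the estimate
for any named demographic subgroup, `autoplot()` draws the tree,
`tree_json()` / `tree_dot()` export it, and `tidy()` / `glance()` give
broom-style summaries of a fit.

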