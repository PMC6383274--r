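---
title: "Additive interaction in matched case-control studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive interaction in matched case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addint)
```

## The scientific problem

Two risk factors act *super-additively* when the risk of the doubly
exposed exceeds what the sum of the two single-exposure excess risks
predicts. In gene-environment epidemiology this additive-scale
interaction — not the multiplicative product term of a logistic model —
is the quantity with a public-health interpretation: it measures the
disease burden that removing one factor would spare among carriers of
the other. The motivating application is a 1:1 sex- and age-matched
case-control study of essential hypertension in which the two factors
are a family history of hypertension (FH, a proxy for genetic
predisposition) and abnormal body-mass index (BMI outside the normal
range of the Chinese adult standard).

## Measures

Let OR11, OR10 and OR01 be the odds ratios of the doubly-exposed,
FH-only and abnormal-BMI-only groups against the doubly-unexposed
reference, all from one 2x4 joint-exposure table. Odds ratios stand in
for the risk ratios of the defining formulas — the usual rare-disease
approximation in case-control designs — with the reference risk
normalized to 1. The package computes

* `reri()` — RERI = OR11 − OR10 − OR01 + 1, zero under exact additivity;
* `attributable_proportion()` — AP = RERI / OR11;
* `pure_attributable_proportion()` — PAP = RERI / (OR11 − 1) = 1 − 1/SI;
* `synergy_index()` — SI = (OR11 − 1) / ((OR10 − 1) + (OR01 − 1)).

The four are algebraically locked together; the test suite
property-checks the identities over random OR triples. Where a measure
is undefined (SI with a non-positive denominator, PAP when OR11 ≤ 1) the
functions raise a typed condition rather than returning a sentinel —
silent NaNs in a bootstrap loop are exactly how undefined replicates go
unnoticed.

## Confidence intervals

The published tables motivating this package report 95% CIs for all
four measures without naming a method, so the package takes two
defensible routes and reports both:

* **Delta method** (`delta_ci()`, `estimate_interaction()`): each
  measure is a smooth function of the three log odds ratios; their
  covariance under the shared-reference 2x4 layout has Woolf variances
  on the diagonal and the reference cell's `1/a + 1/b` off the diagonal.
  RERI and AP are propagated on the natural scale; SI on the log scale
  with exponentiated bounds (it is a ratio of excess risks); the PAP
  interval is the monotone transform 1 − 1/SI of the SI interval.
* **Matched-pair bootstrap** (`bootstrap_ci()`): pairs — the design's
  exchangeable unit — are resampled with replacement and the measure is
  recomputed from each replicate's table; percentile intervals are
  returned, with undefined replicates counted and a warning above 20%.
  The seed is a required argument.

A parametric-bootstrap oracle (multivariate-normal draws of the log ORs
pushed through the measure) checks the delta intervals in the tests, and
the two routes are checked to converge on large simulated studies.

For the crude odds ratios themselves the package uses Woolf log-scale
intervals (normal quantile 1.959964 at α = 0.05): they reproduce the
motivating study's printed OR rows to all printed digits, which is the
evidence that this is the method its authors used. Zero cells are an
error by default; `continuity = TRUE` applies the Haldane-Anscombe +0.5
to all four counts and flags the output.

## Regression for the matched design

`fit_logistic()` is unconditional maximum-likelihood logistic regression
(with sex adjustment in the default pipeline), and
`fit_conditional_pairs()` maximizes the conditional likelihood for 1:1
pairs — equivalent to logistic regression on within-pair differences,
and for one binary exposure the classical discordant-pair ratio. The
motivating study describes a "multilevel" model whose random-effect
structure it never states; a random-intercept model is therefore not
implemented, and the two estimators above are offered as the
design-respecting choices. The saturated joint-exposure fit
(`joint_exposure_design()`) reproduces the crude 2x4 ORs and their Woolf
CIs exactly (same variance formula) — an identity the acceptance tests
exercise on random tables. Rank deficiency is reported with the
offending terms; separation raises a typed error rather than returning a
diverged fit.

## Category codings

BMI categories follow the Chinese adult standard with half-open
intervals [18.5, 24.0), [24.0, 28.0) kg/m², below and above. The source
text leaves the fractional gaps 23.9-24.0 and 27.9-28.0 unassigned and
puts 28.0 itself "over"; the half-open convention closes the gaps and
assigns 28.0 to obese, keeping the partition exhaustive — a package
decision, tested at every boundary. The interaction analysis
dichotomizes BMI as normal versus abnormal with abnormal = {low,
overweight, obese}, following the joint-exposure layout of the
motivating study. WHR abnormality is > 0.90 (men) / > 0.80 (women),
the normal side inclusive of the cutoff.

## The synthetic-data generator

`simulation_config()` defines the generative model the validation rests
on: continuous BMI ~ N(23.5, 3.2²) kg/m² (the control-group scale of the
motivating study), FH prevalence 0.62 among normal-BMI subjects
(optionally associated with abnormal BMI on the odds scale, independent
by default), sex Bernoulli(0.5), age truncated-normal (62, 10.7²) on
[28, 87], and disease from a logistic model with baseline log-odds −2.2,
FH effect log(4.986), category effects log(1.528)/log(3.333)/log(7.312)
— the published main-effect ORs — plus an extra log-odds term
`beta_int` for the FH-and-abnormal-BMI state. Height is N(163.1, 8.0²)
cm; weight is back-solved from BMI and height; waist and hip are linear
in BMI (slopes 2.5 and 2.0 around the BMI mean, residual SDs 6.5 and
6.9) — plausible constants chosen to land in the published mean/SD
ranges, not estimated from any data. Measurements are rounded to
instrument precision (0.1 cm/kg, whole years), which also makes CSV
round trips exact.

Because disease depends on FH and BMI category only through a
finite covariate grid, the model-implied joint-exposure odds ratios are
computed *exactly* by summing case and control mass over the grid
(`theoretical_measures()`); no Monte-Carlo integration error enters the
ground truth. The abnormal cells aggregate three BMI categories, so
their implied ORs are genuine mixtures — the generator does not assume
the estimand it is supposed to test. `calibrate_beta_int()` root-finds
the `beta_int` at which the implied RERI hits a target; the default
configuration is calibrated to RERI 5.67, the motivating study's
headline, giving implied ORs (13.23, 4.99, 3.57). The calibrated value
is mildly negative: the multiplicative main effects alone would already
be super-additive.

Matching is emulated directly from the stated eligibility criteria —
for each sampled case one unused control of the same sex within 5 years
of age — rather than by propensity machinery. Sex and age are
independent of the exposures in the generator, so matching on them does
not distort the exposure odds ratios; real confounded data would not
enjoy this, which is precisely what the conditional-logistic route is
for. What the generator does *not* emulate: FH misclassification from
questionnaire recall, secular BMI trends, the unanalyzed lifestyle
covariates (these can only appear as noise), or any random-effect
clustering — so passing tests validate the estimators under the stated
design, not robustness to those features of real data.

## Numerical and design choices

* Logistic fits: IRLS to tolerance 1e-12, 100-iteration cap; covariance
  from the observed information; separation and rank checks precede
  reporting.
* The Welch (unpooled) t is used for summary comparisons; with the equal
  group sizes of the motivating tables it coincides with the pooled
  form, an identity the tests assert.
* Pearson chi-square without continuity correction. The motivating
  study's printed chi-squares for FH and BMI (80.048, 63.165) are not
  reproduced by any standard Pearson computation on its own printed
  counts (78.94, 62.30 here); the package stands behind the recomputed
  values and the analysis driver says so rather than chasing an
  unstated variant.
* The published 2x4 counts are kept exactly as printed even though the
  doubly-exposed row is inconsistent with its own printed OR (12.993
  back-calculates to control count 71, not 70) and the column totals
  exceed 342 + 342. Interval-requiring analyses of the published table
  use the consistency-corrected count, labelled as such.
* Operating characteristics (analysis/04) use 200 replications of
  342-pair studies per scenario — enough to bound relative bias at the
  10% level and coverage within a few points, while keeping the run in
  the low minutes on one core.

## Worked example

```{r example}
tab <- study_joint_counts()
or_table(tab)
o <- published_or_triple()
interaction_measures(o[["or11"]], o[["or10"]], o[["or01"]])
```

```{r simulate}
cfg <- simulation_config(n_pairs = 342, seed = 1)
theoretical_measures(cfg)
ds <- simulate_matched_study(cfg)
estimate_interaction(build_exposure_table(ds), continuity = TRUE)
```

## Known limitations

* Odds ratios approximate risk ratios; with hypertension prevalence far
  from rare, RERI on the OR scale overstates its risk-scale value. This
  is inherited from the measures' case-control usage, not fixable
  in-package.
* The delta method is asymptotic; RERI's sampling distribution is
  right-skewed at 342 pairs with a thin reference cell (about 20 cases),
  which is why the bootstrap is offered alongside and why the recovery
  simulations report both bias and coverage.
* The published regression tables (univariate screening, "multilevel"
  fits, interclass correlation 0.248) depend on raw data and model
  details that were never published; the package provides the fitting
  machinery and validates it against oracles instead of those numbers.
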