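---
title: "Allometric indexation of aortic root dimensions: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric indexation of aortic root dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortanorm)
library(dplyr)
```

## The problem

Echocardiographic aortic root dimensions — the annulus (Ao-a), the sinuses
of Valsalva (Ao-s) and the proximal ascending aorta (Ao-asc), all in mm at
end-diastole — vary systematically with gender, age, height and weight, and
differ between ethnic populations. Clinical guidelines normalise them
ratiometrically by body surface area (BSA, Du Bois formula), which assumes a
linear, origin-through relationship between diameter and BSA. That
assumption fails in practice: BSA indexation typically *overcorrects*,
reversing the sign of the association with body size and even inverting the
between-gender difference.

`aortanorm` implements the alternative: a multivariate allometric
(power-law) model

$$Y_p = a \cdot b^{\,\mathrm{gender}} \cdot \mathrm{age}^{x} \cdot
\mathrm{height}^{y} \cdot \mathrm{weight}^{z},$$

with gender as a dummy (man = 0, woman = 1), age in years, height in cm and
weight in kg. The corrected value is the dimensionless ratio
$Y_c = Y_u / Y_p$ of the measured to the predicted diameter, centred near 1
in the population the model was fitted to. Three published equation sets
(Chinese, Italian, combined) ship with the package
(`builtin_equation_sets()`), and new sets can be fitted to any cohort.

## Fitting: stepwise log-linear regression

Taking logs linearises the model:
$\ln Y_u = \ln a + \mathrm{gender}\ln b + x\ln\mathrm{age} +
y\ln\mathrm{height} + z\ln\mathrm{weight} + \varepsilon$, with
$\varepsilon$ the log-scale measurement/biological error. `fit_allometric()`
performs forward selection with backward elimination on the four candidates
(gender, ln age, ln height, ln weight):

* a candidate enters when its single-term-addition coefficient p-value is
  the smallest and falls below `p_enter` (default 0.05);
* after each entry, any included term with p ≥ `p_remove` (default 0.10) is
  removed, worst first;
* iteration stops at a fixed point, with ties broken by the fixed candidate
  order, so fits are deterministic.

BSA and BMI are deliberately *never* candidates: both are functions of
height and weight and would confound the original covariates. The intercept
is always retained; a single-gender cohort silently drops the gender
candidate. Back-transformation gives $a = e^{\hat\alpha}$,
$b = e^{\hat\beta_{\mathrm{gender}}}$ and exponents equal to the retained
log-covariate coefficients (exactly 0 for excluded terms). The defaults
`p_enter = 0.05`, `p_remove = 0.10` are the conventional stepwise settings
of mainstream statistical software; both are arguments.

## Cohort construction

Two populations are made comparable by 1:1 propensity-score matching on
gender and age (`propensity_match()`): a pooled logistic model supplies the
propensity, and greedy nearest-neighbour matching without replacement runs
on the logit scale, processing the smaller population in seeded random
order. A caliper is off by default; `"auto"` applies the conventional
0.2 × SD of the logit propensity. Greedy matching is deterministic given
the seed and standard practice; optimal matching is out of scope. When the
propensity model separates the populations completely there is no common
support: with a caliper the result is simply zero pairs, without one the
function refuses and suggests exact matching or a caliper.

Each analysis cohort is split at 7:3 (`split_ab()`) into a construction
group A and a validation group B by a seeded uniform permutation; group A
takes `floor(0.7 n)` subjects, so n = 910 gives exactly 637/273.
Age strata for descriptive comparisons are young (18–40 y), middle
(> 40–65 y) and elderly (> 65 y); ages are continuous and the bands are
half-open above 40 and 65 so every age in [18, 79] maps to exactly one
group.

## Judging a correction

On a validation group, `assess_efficacy()` applies two predefined criteria
to a corrected series:

1. **No material residual correlation.** Pearson correlations of the
   corrected values with age, height, weight, BSA and BMI must not be both
   biologically (|r| > 0.20) and statistically (p < 0.05) significant. The
   conjunction matters: at n ≈ 273 a correlation of 0.13 can be
   "significant" yet biologically negligible, and it does not fail the
   criterion.
2. **Information retained.** The corrected values must remain significantly
   correlated (p < 0.05) with the uncorrected measurements — a correction
   that destroys the measurement signal is useless.

Separately from the pass/fail gate, each residual correlation is annotated
as *overcorrected* (r < 0, p < 0.05), *undercorrected* (r > 0, p < 0.05) or
acceptable. `success_rate()` aggregates reports into a percentage.

Reference intervals of the corrected ratio (`reference_interval()`) default
to the empirical 2.5th–97.5th percentile range (n ≥ 40), with
mean ± 1.96 SD as the `normal_theory` alternative; the published intervals
have widths consistent with a 95% reference range rather than a confidence
interval of the mean, and both conventions are offered without asserting
which produced the published values. Classification against an interval
uses closed bounds: a value exactly on a limit is normal.

Measurement reliability uses Bland–Altman bias and 1.96·SD limits of
agreement plus an intraclass correlation. The ICC form is fixed to the
two-way, absolute-agreement, single-measurement coefficient ICC(A,1),
computed from the mean-squares decomposition; the source analyses do not
state which ICC form they used, so the one-way form is available via
`model = "oneway"`.

## The synthetic-cohort generator

No subject-level data from the source cohorts are public, so
`generate_population()` realises the allometric model as a data-generating
process: gender ~ Bernoulli(502/910); age ~ truncated normal
45.5 ± 13.9 y on [18, 79]; height ~ normal per gender; weight induced
through a BMI draw, `weight = BMI · (height/100)²`, with BMI truncated
strictly below 30 kg/m² (the obesity exclusion), which also yields a
realistic height–weight correlation; each diameter is the truth-equation
prediction times $e^{N(0,\sigma^2)}$ with σ = 0.11, matching the dispersion
of published corrected values (SD ≈ 0.112–0.127). Height and BMI marginals
(chinese_like: men 170 ± 6 cm, women 158 ± 6 cm, BMI 23 ± 2.5;
italian_like: 176 ± 7 / 163 ± 6, BMI 24.5 ± 2.5; combined_like midway) are
plausible adult values chosen once — the source demographic table is not
public — and are fully configurable.

What the generator does *not* emulate: measurement-level echo artifacts,
diseased or dilated aortas, secular height trends, or any dependence of the
noise on covariates. Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes, not that the assumptions hold in any
real population.

### Identifiability of individual exponents

A caveat worth stating precisely. At realistic adult covariate spreads the
log-height SD is only ≈ 0.04, so the sampling SE of a height exponent at
n = 637 and σ = 0.11 is ≈ 0.11/(√637 · 0.04) ≈ 0.11–0.13 — before the
height–weight collinearity induced by weight = BMI·h² inflates it further.
Individual height/weight exponents therefore cannot be pinned down to
±0.05 by any estimator at these sample sizes; what is stable is the fitted
*prediction*: across the nine built-in truths the fitted and generating
models agree to < 2.5% mean absolute log-ratio, and the well-identified
components (gender factor b, age exponent) recover closely. The test suite
checks exactly this decomposition: prediction equivalence as a guaranteed
property, strict per-exponent recovery as a documented stress test that
fails for the height-bearing equations for the reason above.

## End-to-end pipeline and problem sizes

`run_pipeline()` chains the stages: (optional) matching → pooling →
three 7:3 splits → nine stepwise fits on the construction groups → efficacy
reports for the allometric and the BSA correction on the validation groups
(3 parameters × 3 populations × 2 methods = 18 cells) → reference
intervals. All randomness flows from named integer seeds; two runs with the
same inputs and seed are identical, including serialized JSON.

The simulation sizes used throughout the package's own checks are the study
conditions: 910 subjects per population (637/273 split; 546 validation
subjects in the pooled cohort), σ = 0.11. A full pipeline run takes about a
second; the bundled acceptance script averages its summary quantities over
10 replicate runs, since single-draw quantities gated on the maximum of 45
sample correlations have visible Monte-Carlo variability.

```{r example}
specs <- default_population_specs()
chinese <- generate_population(specs$chinese_like, n = 910, seed = 1001)
italian <- generate_population(specs$italian_like, n = 910, seed = 2001)
res <- run_pipeline(chinese, italian, seed = 1, match = FALSE)
res$success_rates
res$fits$chinese$ao_a$equation
```

## Numerical conventions and degenerate inputs

* Units are fixed — years, cm, kg, mm — and conversion is the caller's
  responsibility; the built-in equations are only dimensionally consistent
  with these units.
* Natural logs throughout; excluded covariates are exponent-0 (gender
  b = 1), so predictions never require covariates the model does not use.
* Constant series: correlations error (undefined), ANOVA on a constant
  response returns F = 0, p = 1, constant reference intervals are flagged
  degenerate, and zero between-subject variance makes the ICC an error.
* Non-positive heights, weights, ages, diameters or BSA values are domain
  errors, not NaNs.
* p-values in formatted reports print to three decimals with `<0.001`
  flooring, as in clinical tables.

## Known limitations

* Fitted equations are population-specific; the built-in sets should not be
  extrapolated to other ethnic groups, ages outside 18–79 y, or BMI ≥ 30.
* The greedy matcher does not reproduce any particular published cohort
  reduction; the discard rule used to arrive at published matched cohorts
  is not documented in the source.
* The success criteria inherit the arbitrariness of the |r| > 0.20
  threshold; it is exposed as an argument (`r_threshold`) rather than
  hard-coded.
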