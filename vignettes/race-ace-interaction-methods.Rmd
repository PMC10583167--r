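---
title: "Methods: survey-weighted risk-ratio models and excess-case interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-weighted risk-ratio models and excess-case interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyreri)
```

This vignette is the package's own account of its statistical machinery:
the estimators, the choices made where the methodology literature leaves
room, and what the synthetic-data validation does and does not establish.

## 1. The estimation problem

The package targets effect-measure modification of the association
between elevated adverse childhood experiences (ACEs) and binary adult
health outcomes across racial groups, in a cohort sampled with a
stratified, clustered, weighted design. Two summaries are produced for
each non-referent group:

* **relative scale** — the within-group risk ratio (RR) for elevated
  ACEs and the interaction RR (ratio of a group's RR to the referent
  group's);
* **absolute scale** — excess outcome cases per 1000 exposed
  attributable to interaction, derived from the relative excess risk due
  to interaction (RERI).

Both are functionals of one regression per outcome.

## 2. Modified Poisson regression with design-based variance

`mpreg()` fits a log-link Poisson working likelihood to the binary
outcome by weighted IRLS. The Poisson likelihood is deliberately
misspecified — it is used only as an estimating equation whose solution
is the log-RR vector — so all inference rests on the sandwich
covariance. The design-based variant used here aggregates weighted score
contributions `w_i (y_i − mu_i) x_i` into per-cluster totals, centers
them within stratum, applies the `n_h/(n_h − 1)` correction (with `n_h`
the number of clusters in stratum `h`), and sums across strata. This is
the standard Taylor-linearization estimator for a stratified
cluster-sampled GLM; with one observation per cluster and one stratum it
collapses to the familiar HC-style robust covariance (the test suite
verifies both this equivalence against an independent implementation and
the closed-form log-RR standard error on a saturated 2×2 design).

Numerical choices:

* **Start**: intercept at the log weighted prevalence, all other
  coefficients zero. Step-halving (up to 10 halvings) guards the
  iteration when a Newton step increases the working deviance, which can
  happen on the log link because fitted risks are unconstrained.
* **Convergence**: maximum relative coefficient change below `1e-10`,
  at most 100 iterations. Non-convergence is an error carrying the tail
  of the relative-change trace.
* **Fitted risks above 1** are permitted during fitting and flagged —
  never clipped — on prediction output; this is intrinsic to the
  modified Poisson approach.
* **Separation**: a covariate cell with no observed events drives its
  log-risk coefficient to `−∞`; the information matrix eventually turns
  numerically singular and the fit stops with a diagnostic error rather
  than returning a boundary estimate. This matters in practice: cells
  such as (smallest race group) × (rare outcome) × (exposed) can have
  single-digit expected counts at realistic cohort sizes, so Monte-Carlo
  studies in the tests and acceptance script skip and count
  non-converged replicates instead of silently absorbing them.
* **Single-cluster strata** contribute zero variance by default
  ("certainty stratum", with a warning); a strict mode errors instead.
  No finite-population corrections are applied.

Weight-scale invariance (multiplying all weights by a constant changes
neither coefficients nor the sandwich) holds by construction and is
tested.

## 3. Multiple imputation and pooling

`impute_chained()` is a compact chained-equations engine, documented as
such rather than a re-implementation of any particular imputation
package: binary fields are imputed by logistic regression with an
approximate-posterior coefficient draw, five-level ordinal fields by
proportional-odds draws, continuous fields by Bayesian normal linear
draws with posterior-predictive noise (squeezed into the observed range
so proportions and concentrations stay valid). ACE components are
imputed at component level; the score is summed and dichotomized only
afterwards, so imputation uncertainty propagates into the exposure.

Two policies are configurable because the applied literature is split:

* **weights** enter imputation models as a predictor (log weight)
  rather than as fitting weights — the common pragmatic choice for
  weight-naive engines;
* the **predictor set** defaults to race, log weight, core covariates
  and all seven outcomes (outcomes must be in the imputation model for
  the analysis model to be congenial); ACE components additionally
  predict one another.

Default `M = 20` imputations with 10 cycles mirrors the analysis the
package was built around; tests use smaller values, which only weakens
(never biases) the pooled inference. `rubin_pool()` implements the
classical rules exactly: `T = W + (1 + 1/M)B` with per-term df
`(M−1)(1 + W/((1+1/M)B))²`; a term with numerically zero
between-imputation variance gets infinite df and a normal reference.
Linear-combination CIs (e.g. within-group RRs) recompute the Rubin df
for the combination from the pooled `W` and `B`.

## 4. From interaction RR to excess cases per 1000

With referent group `r`, exposure indicator `X` and group `g`, the model
gives three risk ratios sharing the doubly-unexposed cell `(r, X=0)` as
baseline: `RR_g1`, `RR_g0`, `RR_r1`. Then

```
RERI = RR_g1 − RR_g0 − RR_r1 + 1
IC   = RERI × R00
excess cases per 1000 = 1000 × IC
```

`R00` is the model-predicted risk in the doubly-unexposed cell. Two
standardizations are offered because RERI-to-IC conversion is the one
genuinely ambiguous step in this chain:

* **reference profile** (default): predict at a single covariate
  profile, by default every adjustment covariate at its survey-weighted
  mean (`reference_profile()`);
* **marginal**: average predicted risk over a supplied set of
  doubly-unexposed covariate profiles.

The default was chosen for transparency — it makes `R00` a single
interpretable number — and the alternative is one flag away; on the
synthetic cohorts the two agree closely because covariate effects on the
log scale are modest.

Confidence intervals are **percentile intervals over multivariate-normal
draws** of the coefficient vector with the pooled total covariance `T`
(default 10,000 draws, seed-reproducible). Drawing from the single
pooled Gaussian, rather than resampling within imputations, is the
simplest scheme consistent with pooling-then-resampling; per-imputation
draws would require retaining all `M` fits and is not implemented.
Percentile (not bias-corrected) endpoints are used. The tests check that
the Monte-Carlo interval width agrees with an independent delta-method
computation within 10% on a toy fit, and that doubling the draw count
moves endpoints by under 2%.

A documented subtlety: the *sign* of the excess-case estimate follows
RERI, not the interaction RR. An interaction RR below 1 can coexist with
positive RERI (and vice versa) when the group main effect is large; the
test suite contains constructed counterexamples of both kinds.

## 5. Derived variables

* **ACE score**: sum of ten binary components, exposure = score ≥ 4.
  Scoring refuses missing components — encountering one means the
  imputation stage was skipped, which the pipeline treats as a
  programming error, not a data condition.
* **Metabolic syndrome**: 3+ of 5 categories — hypertension (systolic
  ≥ 130 or diastolic ≥ 80 mmHg, diagnosis, or medication), waist
  (> 102 cm male / > 80 cm female), triglycerides at or above the
  sex-specific upper decile boundary (top 3 deciles male / top 2
  female), HDL at or below the lower boundary (bottom 2 male / bottom 3
  female), diabetes (HbA1c > 5.7%, medication, or diagnosis). The
  standalone hypertension outcome reuses category (1) verbatim.
* **Decile boundaries** are survey-weighted, left-continuous
  inverse-CDF quantiles — always observed values, no interpolation — so
  membership rules are exact and weight-scale invariant. They are
  computed within each completed dataset on the analysis sample; whether
  to weight and when to compute relative to exclusions are config
  choices, with these defaults, because source analyses rarely state
  them.
* **Covariates**: equivalized income = household income / √(household
  size); parental education = max of the two parents' five-level
  ordinal; parental support = mean of five Likert items; neighborhood
  disadvantage = mean of five tract proportions (validated to [0, 1]).

## 6. The synthetic cohort generator

`generate_cohort()` emulates exactly the features downstream code
depends on:

* stratified cluster sampling with log-normal, within-stratum mean-1
  weights (`weight_dispersion` = sdlog, default 0.3 — heterogeneous
  enough to distinguish weighted from unweighted code paths);
* five race groups at the weighted shares of the motivating cohort;
* ten exchangeable Bernoulli ACE components whose per-item probability
  is solved from the binomial tail so that P(score ≥ 4) matches each
  group's configured prevalence (default 21–40%);
* seven outcomes drawn under a **log-linear risk model**
  `risk = baseline × race-main RR × (within-group RR if exposed) ×
  optional covariate terms`, so configured RRs are *exactly* the
  estimand of the modified Poisson model — parameter recovery is a sharp
  test, not an approximation. Configurations implying any cell risk
  above 1 are refused at validation and again at generation;
* six confounder blocks, biomarkers on plausible adult scales, a
  pregnancy indicator for females (rate 0.073, to exercise the rule
  that drops pregnant participants from the two biomarker-based models
  only);
* missingness: by default rows acquire at least one masked ACE
  component / covariate / outcome at rates 0.55 / 0.21 / 0.40 — the
  observed row-level missingness pattern of the motivating study —
  under MCAR, with a MAR option (masking depends on race and parental
  education, intercept calibrated to the marginal rate) for imputation
  stress-tests. Design variables are never maskable.

What the generator does **not** emulate: the real school-based sampling
frame and non-response weighting, correlation among ACE components
beyond exchangeability, correlation among outcomes given covariates, and
questionnaire-level measurement. Consequently, passing recovery tests
demonstrates the estimators are correct for the declared data-generating
process; it does not certify robustness to the dependence structures of
real survey data.

## 7. Validation scale

The test suite and acceptance script size their simulations to run on a
single CPU in minutes, as the package's own reproducibility budget:
oracle and identity checks are exact and instantaneous; coverage
properties use 120–500 replicates of small cohorts (n = 400–2,000);
parameter-recovery studies use 200 replicates of n = 12,000 cohorts
(the motivating study's scale) with M = 2 and 2,000 resamples, passing
when the Monte-Carlo mean is within 3 Monte-Carlo standard errors of
generator truth. Non-converged replicates (separation in the smallest
cells; a few percent of replicates at these sizes) are skipped and
counted, and replication continues to the target count.

## 8. Known limitations

* The log link on binary outcomes is unstable in near-empty cells; rare
  outcome × smallest group analyses may simply not converge, as in the
  anxiety model for the smallest groups at realistic sizes. This is
  surfaced as an error, never silently patched.
* The chained-equations engine is intentionally minimal: no predictive
  mean matching, no multilevel structure, no convergence diagnostics
  beyond iteration counts.
* Resampling CIs assume approximate multivariate normality of the
  pooled coefficients; with very few imputations and high missingness
  the Gaussian approximation to `T` is the binding assumption.
* One model per outcome is fit independently, with no multiplicity
  adjustment — interpretation rests on CI coverage, matching the
  analysis style the package reproduces.
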