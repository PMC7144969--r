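---
title: "Validating cardiovascular mortality risk equations in older persons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cardiovascular mortality risk equations in older persons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riskvalid` implements the external-validation workflow for fatal
cardiovascular (CV) risk equations of the SCORE family on cohorts of older
persons. This vignette describes the statistical models, the choices made
where conventions were genuinely open, and what the synthetic-data checks do
and do not establish.

## The risk equations

Two functional families are supported, both driven by a JSON coefficient
registry so that coefficient values are data, not code.

**Two-cause Weibull (SCORE).** Each cause of death — coronary heart disease
(CHD) and non-CHD cardiovascular disease — has a Weibull baseline on the age
scale,

    S0(age) = exp(-exp(alpha) * (age - 20)^p),

modified proportionally by a centred linear predictor
`w = beta_chol (chol - 6) + beta_sbp (SBP - 120) + beta_smoker smoker`, so
`S(age) = S0(age)^exp(w)`. The 10-year cause-specific risk conditional on
having survived to the attained age is `1 - S(age + 10)/S(age)`. The two
cause-specific risks are combined assuming independence:

    R = 1 - (1 - R_chd) * (1 - R_nonchd).

The originally published additive combination `R_chd + R_nonchd` can exceed
1 for high-risk profiles — exactly the profiles an older cohort is full of —
and is therefore kept only behind an explicit flag
(`combine_cause_risks(..., rule = "additive_original")`), never silently
clipped, and never used in the validation pipeline.

**Linear predictor on baseline survival (SCORE OP).** Per sex,
`R = 1 - S0(t)^exp(beta'(x - x0))` with declared baseline survivals at the
5- and 10-year horizons and covariates that additionally include diabetes
and HDL cholesterol. If a source publication supplies a parametric baseline
instead of per-horizon values, the transcriber computes `S0(5)` and `S0(10)`
once at transcription time; the engine stays uniform across horizons.

Registry notes. The shipped SCORE blocks are transcribed from the 2003
development publication (cited in each block's mandatory `provenance`
string). The shipped SCORE OP blocks are a **synthetic stand-in** of
realistic sign and magnitude — the file name and provenance strings say so —
because the published SCORE O.P. coefficients, centering constants and
baseline survivals are not reprinted in validation papers and must be
transcribed from the development publication by the user. The package
validates registry *structure* (both sexes present, centering for every
coefficient, declared horizons, non-empty provenance), not values.

Ages outside the equations' development ranges (above 65 for SCORE, 80 for
SCORE OP) are evaluated at face value with a warning: validating the scores
in a cohort aged 70+ is the entire point, and the warning keeps the
extrapolation visible rather than hidden. Exact attained age enters the
formulas (cohort ages are integer by default, as assessed in interviews; the
generator has a flag-free continuous path only internally before rounding).

## "Actual" probabilities

Calibration needs an estimate of what actually happened.

- Horizons **inside** the observed follow-up (5-year equations) use each
  decile group's own Kaplan-Meier estimate at the horizon, with Greenwood
  variance. The step function is right-continuous; `S(t)` at an event time
  includes that event. Kaplan-Meier never extrapolates: requesting a horizon
  past the last observed time is an error that points to the Weibull route.
- Horizons **beyond** follow-up (10-year equations against roughly 5 years
  of data) use Weibull regression with the decile group as a categorical
  covariate: a common shape across groups and group-specific scales, fitted
  by maximum likelihood via `survival::survreg`. Projection to 10 years is
  `1 - exp(-(10/scale_g)^shape)`. Whether the emulated analyses shared the
  shape across groups is not documented; common shape is the default (it is
  the standard single-categorical-covariate survival regression, identical
  under accelerated-failure-time and proportional-hazards readings), and
  `shared_shape = FALSE` fits fully separate per-group models instead.
  `weibull_diagnostics()` exposes the `log(-log S)` vs `log t` series whose
  linearity (and cross-group parallelism) supports the model.

Competing non-CV deaths are **censored** at the death time in both
estimators. This deliberately reproduces the validated scores' own
development convention (no competing-risk adjustment) so that predicted and
"actual" quantities estimate the same counterfactual net risk; it means both
are interpretable only under independence of the competing processes. An
Aalen-Johansen style estimator is a natural extension but is not part of
the validation pipeline.

Deaths whose cause could not be ascertained count as non-CV in the primary
analysis; `worst_case_sensitivity()` recodes them all as CV for the opposite
extreme.

## Calibration and discrimination metrics

**Decile grouping** uses empirical quantile cutpoints with ties assigned to
the lower group — deterministic and near-equal group sizes; heavily tied
risks collapse groups with a warning rather than fail.

**Calibration-in-the-large** sums expected events `n_g * pbar_g` and actual
events `n_g * a_g` over groups; totals are displayed as integers but the
predicted/actual ratio is computed on unrounded totals and reported to two
decimals.

**Nam-D'Agostino chi-square**:
`sum_g n_g (a_g - pbar_g)^2 / (pbar_g (1 - pbar_g))`, referred to a
chi-square with `df = G` — the external-validation convention (no parameters
were estimated on the validation data). The df convention is surfaced in
every report rather than hidden, and a Greenwood-variance variant
(`variance = "greenwood"`) is available since the binomial denominator
understates the variance of a censored Kaplan-Meier estimate. In simulation
the binomial form is mildly anti-conservative under ~15% censoring
(rejection around 7-8% at nominal 5%); this is a property of the statistic
as conventionally used, not a defect of the implementation.

**Harrell's C** over the entire observed follow-up, computed by an O(n^2)
compiled pair scan. Conventions: the reference of a pair is the earlier
event (or the event at a tied time when the other is censored); tied event
times are incomparable; tied risks score half. An exhaustive enumeration
reference implementation lives in the test suite and the two agree exactly
on hundreds of random censored instances; `survival::concordance` serves as
an additional independent cross-check.

**BCa bootstrap** intervals resample participants (rows), never residuals;
decile groups are re-formed inside each resample when the statistic depends
on grouping. Bias correction `z0` comes from the share of bootstrap
replicates below the point estimate, acceleration `a` from the jackknife
third-moment formula. For the C-index the leave-one-out values come from a
single O(n^2) pass (each pair's credit is attributed to both members), so
the jackknife costs O(n) afterwards instead of n full concordance
computations. All bootstrap draws are governed by a single seed recorded in
the report; the same seed reproduces reports byte-identically.

## The synthetic cohort generator

`generate_baseline()` draws independent truncated-normal continuous
covariates (age rounded to integers, bounded at 70) and Bernoulli binaries
with sex-specific means matching the emulated study's published marginals
(n = 1,657; 734 men; mean age 79.7 (SD 6.7); SBP 147.0 (22.8) mmHg; total
cholesterol 5.6 (1.2) mmol/l; HDL 1.5 (0.5); smoking 5.2%; diabetes 25.0%).
Only marginals are published, so covariates are independent by default; a
user covariance can be injected by editing the spec, and any injected
correlation is a modelling choice, not an observed quantity.

`simulate_followup()` draws latent CV and non-CV death times from two
proportional-hazards Weibull models (`scale_i = scale0 * exp(-lp/shape)`),
an exponential loss-to-follow-up time (hazard 0.005/year), and a fixed
administrative censoring horizon of 5.2 years; the observed record is the
earliest. A fraction 44/324 of deaths has its recorded cause masked to
"unknown" independently of the true cause — the simplest mechanism
consistent with an agnostic worst-case analysis — while the truth is kept in
hidden audit columns that never serialize without a debug flag. Baseline
scales (36.3 years CV, 25.8 non-CV at the centred profile) were calibrated
once with `scripts/tune_generator.R` so the default scenario reproduces the
emulated rate environment — about 16 recorded CV deaths and 44 deaths per
1,000 person-years, median follow-up ~5 years — and then frozen; they are
not re-tuned per run.

`true_probability()` gives the closed-form net CV risk
`1 - exp(-(t/scale_i)^shape)` ignoring competing events: the generator's
analytic oracle. Feeding these true probabilities through the full pipeline
is the end-to-end self-consistency check: the predicted/actual ratio centres
on 1 and the Nam-D'Agostino test rejects at roughly its nominal rate. Two
caveats define what this does *not* show. First, the check runs with cause
masking off, because a score that predicts true CV death cannot be perfectly
calibrated against partially mislabelled outcomes — with the default 13.6%
masking the same oracle shows a ~1.16-fold apparent overestimation, which is
itself a useful illustration of outcome misclassification. Second,
synthetic covariates are independent and exactly Weibull; real cohorts have
correlated risk factors, non-Weibull hazards and informative censoring, so
passing these checks demonstrates correctness of the machinery, not
transportability of any equation.

One visible consequence of covariate independence: the Spearman correlation
between an equation's high- and low-risk regional variants, essentially 1.00
for the linear-predictor family, comes out near 0.99 rather than above it
for the two-cause family, because the regional baselines reweight the two
causes' linear predictors slightly differently and independent covariates
maximise the resulting rank churn.

## Numerical choices and degenerate inputs

- Weibull fitting tolerances and starting values are `survreg`'s defaults;
  times are floored at 1e-8 years since the likelihood needs strictly
  positive times. A decile group with zero events stays in the fit (its
  likelihood contribution is censoring-only) with a warning.
- Poisson exact rate intervals use the Garwood chi-square inversion, which
  matches `poisson.test` to machine precision.
- Exclusion flow: a record failing several inclusion criteria is counted at
  the first in the order prior-MI / missing risk factors / no follow-up, the
  standard flow-diagram accounting. The emulated study pools its exclusions,
  so any attribution is consistent with it; counts always sum to
  input n − output n. Missing data are handled complete-case only — no
  imputation — matching the validation design.
- Unit conversion divides mg/dl cholesterol by 38.67 on read; multiplying
  back recovers the input to representation error.
- BCa degenerates gracefully: if the bootstrap distribution lies entirely on
  one side of the point estimate, the percentile interval is returned.

## Problem sizes used by the test suite

The shipped checks run at sizes chosen to give stable Monte-Carlo behaviour
on a single CPU: concordance oracle equivalence on 200 random instances of
n ≤ 50; Weibull parameter recovery at n = 2,000 per group with ~40%
administrative censoring (shape within 10%, 10-year probabilities within 2
percentage points); BCa coverage for a mean on 1,000 exponential samples of
n = 50 at B = 1,000 (coverage in the 93-96% band typical of BCa at this n);
and 200 end-to-end replicates of the default n = 1,657 scenario at B = 200.
The acceptance script runs the full six-equation validation at B = 2,000,
the bootstrap size used for reported intervals.

## Known limitations

- No competing-risk calibration route; net-risk interpretation rests on
  independence of CV and non-CV death processes.
- No recalibration (intercept/slope updating), reclassification or
  decision-curve utilities; the package quantifies transportability, it does
  not repair it.
- The SCORE OP registry entries shipped are synthetic stand-ins; conclusions
  about the real SCORE OP require a user-supplied transcription.
- Kaplan-Meier actuals require the horizon inside observed follow-up by
  design; the Weibull projection's validity beyond follow-up is exactly as
  good as the Weibull assumption, which is why the diagnostic series are a
  first-class output.
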