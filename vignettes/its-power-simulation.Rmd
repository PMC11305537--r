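---
title: "Power, bias and precision of short interrupted time series designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power, bias and precision of short interrupted time series designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itspower)
```

## The question

An interrupted time series (ITS) design estimates the effect of a shock by
extrapolating the pre-intervention trend and comparing it with the observed
post-intervention series. With long series and a single clean intervention
this is well understood. `itspower` targets the harder regime that arises
in, for example, educational testing during pandemic school closures: 6–20
measurement occasions, two interventions close together, effects of a few
percent of the annual learning gain, and a fitted model that may omit terms
the data contain (underfit) or carry terms they lack (overfit). The package
answers design questions empirically: for a given effect size, how many
subjects per occasion and how many occasions give adequate power, and what
do misspecified models do to bias and precision?

## The generative process

Scores follow a linear growth process per measurement occasion:

* the occasion-1 score is centred on `baseline_mean` = 170 score units with
  between-subject variance `baseline_var` = 25;
* each subsequent occasion adds `slope` = 16.5 score units (the annual
  growth rate of the motivating test scale; the unit of `slope` is score
  units per occasion);
* independent occasion-level noise with variance `noise_var` = 25 is added
  to every record;
* intervention effects are a fraction `effect_size` of the slope and enter
  as negative shocks: a step change and/or slope change of
  `-effect_size * slope`, and optionally a second step equal to
  `second_step_fraction` = 0.5 of the first.

Time is centred so that the first intervention sits at 0, between the two
middle occasions — occasions map to the half-integers
`-(T-1)/2, …, +(T-1)/2`, which forces an even number of occasions and makes
the step coefficient the jump exactly at the boundary. A second
intervention, when present, is placed after occasion
`k = floor(0.75 T + 0.5)` (round half up at 75% of the series). The number
of occasions between and after the two boundaries then alternates with the
parity of `k`, which is what drives the oscillation in the underfit step
bias shown below. Because at most two occasions ever follow the second
boundary, the second intervention carries only an incremental step in the
default two-intervention model; its post-slope term is available in the
`combined`/`two_intervention_full` variants for longer series (it is
collinear with the second step when only one occasion follows the
boundary, and the fitter reports exactly that).

Two sampling modes are provided. The default, `cross_sectional`, draws a
fresh baseline deviation for every (subject, occasion) record, so all
`n × T` records are independent — under pooled OLS this yields exactly
nominal type-I error for null coefficients, which is the calibration
behaviour the simulation is designed to reproduce. The `longitudinal` mode
draws one baseline deviation per subject and shares it across occasions,
giving persistent growth curves; pooled OLS then underestimates standard
errors because records are positively correlated within subject, and a
user choosing this mode should interpret rejection rates accordingly. The
default is cross-sectional for exactly this reason: it is the mode under
which the plain-OLS inference the package implements is calibrated.

What the generator deliberately does **not** emulate: autocorrelated noise
beyond the shared subject intercept, heterogeneity in individual growth
rates, unequal occasion spacing, missing data, and occasion-varying sample
sizes. Passing tests therefore certify the estimator's behaviour under
clean, balanced panels; real test-score data with cohort effects or
drifting participation can behave worse, and the power numbers here are
best read as upper bounds for such data.

## The model catalogue

All models are ordinary least squares on individual records (`n` enters
through `N = n T`), with classical homoskedastic standard errors and
two-sided t tests. The variants, by the terms they carry:

| name | terms |
|---|---|
| `basic` | intercept, T, X1, T·X1 |
| `two_intervention_steps` | intercept, T, X1, X2, T·X1 |
| `quadratic` | basic + T² |
| `two_intervention_full` | intercept, T, X1, T·X1, X2, T·X2 |
| `combined` | two_intervention_full + T² |

The six studied (shape, model) pairings — `simulation_pairings()` — cover
one right fit, three overfits and one underfit of the basic model plus the
corrected two-intervention fit. The second step is coded additively: the
`step2` coefficient is the *incremental* second drop, and the total level
change since the second intervention (`step + step2`) is reported as a
derived contrast on any fit containing both.

No robust, clustered or autocorrelation-corrected inference is applied:
with very short series, plain OLS is the estimator under study, and the
calibration property above is part of what is being measured.

## Performance criteria

For every coefficient of every cell, over `reps` replications:

* **power** — the share of replications with two-sided p < α (strictly),
  α defaulting to 0.05. For a coefficient whose generative value is zero
  this is the empirical type-I error.
* **bias** — `|mean(estimate) − true value|`: errors are averaged before
  the absolute value, so the smooth bias surfaces reflect systematic
  displacement, not sampling spread. The empirical SD of the estimates is
  reported alongside.
* **precision** — the mean model-based standard error. The empirical SD
  column lets a user check the two agree where the model is right.

A term fitted but absent from the generating process has true value 0; the
bias of the underfit basic model's step is measured against the *first*
generative step.

## Numerical design

The design matrix is constant within a cell — only the response changes —
so the engine factorises it once (QR) and solves all replications as one
multi-response least-squares problem. This is algebraically identical to
refitting each replication and is verified against both an explicit
normal-equations solve and `lm()` in the test suite. Rank deficiency is
detected from the QR rank at R's default relative tolerance (1e-7) and
reported with the names of the collinear terms. Noiseless panels
(both variances zero) are legal and fit with zero residual, which the
exact-recovery tests exploit.

Every replication seed is a deterministic function of
(base seed, scenario index, shape, replication index) — a 31-bit multiply-
add chain — so any single panel can be regenerated in isolation, results
are independent of execution order and chunking, and panels are *shared*
across fitted models within a (scenario, shape, replication) triple. The
last property makes overfit-vs-right-fit comparisons paired, which is how
the overfit power-loss test achieves its sensitivity. The fitted model is
deliberately excluded from the seed for this reason.

Replications default to 1000, the grid to 8 × 8 × 6 = 384 scenarios
(T = 6–20 by 2, n = 100–1500 by 200, effects 1–30% of the slope) across
four shapes. The test suite and the acceptance script run individual cells
at 300–1000 replications — cells at the largest headline sizes
(n = 1500, T = 14) take on the order of a second each with the factorised
solver, so the suite stays desk-scale while keeping Monte Carlo error
bands (3 binomial SEs) tight enough for the qualitative assertions.

## Design choices that were genuinely open

* **Frontier strictness.** "Adequate power" is power strictly above the
  0.80 threshold in `minimum_requirements()` (configurable, with a
  non-strict option); reported frontier pairs are Pareto-minimal in
  (subjects, occasions).
* **Bias aggregation.** `|mean error|` rather than `mean |error|`; the
  latter conflates bias with spread and would not vanish for an unbiased
  estimator.
* **Precision.** The mean model-based SE, with the empirical SD kept as a
  diagnostic rather than folded in.
* **Failure policy.** A cell tolerates up to 1% failed fits (non-finite
  estimates), counting and reporting them; beyond that it errors. With a
  full-rank fixed design, per-replication failures cannot actually occur —
  the ceiling guards configuration mistakes, not numerics.
* **Underfit bias directions.** The expected coefficients of a misspecified
  fit are the projection of the generative mean onto the model's column
  space, which the tests compute in closed form. Ignoring a second
  (negative) step yields a *signed overestimate* of the first step (a
  smaller estimated drop) and a *signed underestimate* of the slope change
  (a steeper estimated decline): the absorbed late drop tilts the fitted
  post-slope down and pushes the fitted boundary level up. These exact
  directions, their parity oscillation in T, and the overall decline of
  the step bias with longer series are asserted analytically, with the
  Monte Carlo cell checked against the projection.

## Known limitations

* Inference options are deliberately minimal: no multilevel, SEM or
  ARIMA-style estimators, and no robust standard errors. In longitudinal
  sampling mode the reported rejection rates are therefore not calibrated
  type-I errors.
* The adequacy frontiers scale directly with the noise-to-effect ratio;
  with the default variance constants the headline cells sit well inside
  the adequate region, and users studying noisier instruments should set
  `baseline_var`/`noise_var` to their own scale rather than reuse the
  defaults.
* The 75% placement rule reproduces the qualitative parity pattern but is
  one of several defensible roundings of "75% of the series"; the
  between/after occasion counts it induces are documented above rather
  than asserted as the only reading.
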