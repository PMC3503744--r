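---
title: "Methods: quantifying attrition bias with a latent-liability path model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying attrition bias with a latent-liability path model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attrisim)
```

## The model

Longitudinal cohorts lose participants, and the participants they lose are
rarely a random sample. `attrisim` studies the consequences with the
smallest model in which the problem can be posed exactly: three jointly
normal standardized variables,

* `X` — a baseline predictor,
* `Y = a X + e_Y` — the follow-up outcome, with population regression
  slope `a`,
* `L = b X + c Y + e_L` — a continuous latent *liability of dropping
  out*, depending directly on the baseline (`b`) and on the follow-up
  outcome itself (`c`).

All three variables have unit variance, so the implied correlations are

```
rho_XY = a,   rho_XL = b + a*c,   rho_YL = c + a*b
```

and the residual variance of `L` is `1 - b^2 - c^2 - 2abc`
(`path_model()` refuses parameter combinations that would make any
residual variance negative). Complete-case analysis observes `(X, Y)`
only for units whose liability falls below a threshold.

```{r}
m <- path_model(a = .10, b = .40, c = .40)
m
implied_moments(m)
```

## Closed-form expectations under selection

Retaining a fraction `p` corresponds to conditioning on `L < t` with
`t = qnorm(p)`. Write `h = dnorm(t)/pnorm(t)` for the inverse Mills
ratio. Standard truncated-normal results give

* retained mean of the outcome: `E[Y | L < t] = -rho_YL * h`,
* liability variance after selection: `Var(L | L < t) = 1 - t*h - h^2`,
* and, with `theta = 1 - Var(L | L < t)`, the probability limit of the
  complete-case OLS slope of `Y` on `X`:

```
slope_cc = (a - theta * rho_XL * rho_YL) / (1 - theta * rho_XL^2).
```

These are exposed as `analytic_retained_mean()` and
`analytic_retained_slope()` and serve as the oracle for every Monte Carlo
result in the package.

```{r}
rule <- retention_rule(retain = .50)
analytic_retained_mean(m, rule)
analytic_retained_slope(m, rule)
```

Two selection modes are provided. `"rank"` mode (the default, matching
how attrition is usually imposed in simulation studies) keeps exactly
`floor(p * n)` units with the lowest liabilities; `"threshold"` mode
keeps `L < t`, so the retained count varies binomially. The distinction
matters for validation: conditional on the retained count, threshold-mode
completers are i.i.d. draws from the truncated distribution, so their
mean is *exactly* unbiased for the closed form above, while rank-based
selection carries an `O(1/n)` offset (the expected mean of the `m`
smallest order statistics is not the truncated mean). The test suite
therefore probes oracle equivalence in threshold mode and uses rank mode
for the replication grids.

## The Monte Carlo engine

`run_condition()` replicates one condition: simulate `n` units, apply the
retention rule, and record the complete-case mean of `Y` (with its
standard error) and the OLS slope of `Y` on `X` (with its standard
error). Aggregation over `reps` replications reports

* the mean estimate and the Monte Carlo SE of that mean,
* a *mean aggregated CI*: the average of the per-replication
  `estimate ± 1.96 * SE` limits, alongside empirical 2.5/97.5 percentiles
  of the estimates,
* *coverage*: the percentage of per-replication CIs containing the
  population value (0 for the mean, `a` for the slope),
* *rejection*: the percentage of replications with `|slope| > 1.96 * SE`,
  i.e. power against the zero-slope null (or type-I error when `a = 0`
  after selection leaves the slope unbiased).

`run_grid()` crosses the 15 canonical `(c, b)` dependency pairs
(`dependency_grid()`) with attrition rates .30/.50/.70 at a given `a`,
deriving an independent reproducible seed per cell with `cell_seed()`;
`format_tables()` renders the results in the conventional
`estimate (CI) coverage` layout, and `run_paper_replication()` writes the
full table set with a manifest (seeds, versions, runtimes). A 45-cell
grid at 500 replications of `n = 1000` runs in well under a minute.

## Mapping loadings to odds ratios

Liability loadings are on a latent standardized scale; applied readers
think in odds ratios per SD. `beta_to_or(beta, rule)` reports the
pseudo-true logistic coefficient obtained when drop-out (the liability
dichotomized at the attrition quantile) is regressed on a per-SD
regressor correlated `beta` with the liability. It is computed
deterministically by a weighted logistic fit over a fine normal
quadrature grid (a simulation method is also available), and
`or_to_beta()` inverts it numerically. Because planting and recovery use
the same estimand, a generator configured to plant OR 0.59 yields
diagnostics whose estimates converge to 0.59. Note that this mapping is
an approximation to a pseudo-true parameter — the dichotomized-normal
model is not literally logistic — so reported ORs should be read as
calibrated summaries, not exact logistic parameters.

## Attrition diagnostics for real cohort tables

The `attrition_logistic()` / `compare_baseline_correlations()` /
`polyserial_corr()` trio reproduces the standard diagnostic workflow on a
baseline table with 0/1 wave-participation flags:

* continuous predictors are screened for skewness (`e1071` type-2
  estimator against the exact small-sample SE; log transform only when
  skew exceeds twice its SE) and standardized unless exempt (binary
  indicators, age in years) — `standardize_predictors()` with a
  `variable_spec()` table;
* per-SD drop-out odds ratios with Wald CIs, unadjusted or mutually
  adjusted, with Bonferroni-corrected significance and explicit flagging
  of separation/non-convergence rather than silent `NA`s;
* stayer-versus-dropout comparison of baseline correlations with the
  outcome, with an interaction-term p-value and the mean absolute
  discrepancy as an effect-size summary;
* a two-step maximum-likelihood polyserial correlation between each
  continuous baseline variable and the binary drop-out indicator.

## The synthetic cohort generator

`generate_cohort(cohort_config())` draws a cohort of 913 mothers-like
records with known ground truth. Design choices worth knowing:

* **Single-factor latent structure.** Published attrition tables rarely
  include a full baseline correlation matrix. The default builds one from
  each variable's correlation with the distress outcome: the outcome
  loads 0.8 on a common factor and variable `j` loads
  `outcome_corr_j / 0.8`. This reproduces the catalogue's
  variable–outcome correlations exactly and is positive semi-definite by
  construction. Any full matrix can be supplied instead; a non-PSD
  request errors with the distance to the nearest valid correlation
  matrix rather than being silently repaired.
* **Scale bounds and clipping.** Continuous scores are rescaled to
  catalogue means/SDs and clipped at their printed scale bounds; the
  induced mean shift per variable is recorded in the truth object.
  Clipping attenuates observed correlations by a closed-form factor
  (`clip_attenuation()`), so planted marginal odds ratios are solved on
  the *observed* scale via `planted_loading()`, which divides the
  `or_to_beta()` solution by the variable's attenuation factor
  (`catalogue_kappa()`).
* **Binary prevalences** for living alone (8%) and not working (15%) are
  package defaults, not published descriptives.
* **Planted waves.** The default plants sociability (OR 1.45 per SD) on
  one-year drop-out (17%) and education (OR 0.59 per SD) on fifteen-year
  drop-out (56%); rank mode drops exactly 155 and 511 of 913. The truth
  object carries loadings, implied latent correlations, observed-scale
  implied ORs, thresholds and seeds, so every diagnostic can be validated
  against known values. `make_fixture_suite()` writes three small
  deterministic CSV cohorts plus a JSON ground-truth file for unit tests.

## Limitations

* The oracle covers the trivariate-normal, single-threshold world;
  non-normal liabilities or outcome-dependent measurement error are out
  of scope.
* `beta_to_or()` is a pseudo-true logistic parameter, accurate to a few
  percent against fully parametric alternatives, not an exact mapping.
* Aggregated CIs average per-replication limits; for heavily biased cells
  the empirical percentile interval (also reported) is the better
  uncertainty summary.
* The generator's single-factor default cannot encode conditional
  (partial) correlation patterns among predictors; supply a full matrix
  when those matter.
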