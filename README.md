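# attrisim

Monte Carlo assessment of attrition bias in longitudinal studies.

Cohort studies lose participants between waves, and drop-out is usually
*selective*: the people who leave differ on the very outcomes being
studied. `attrisim` quantifies what that does to complete-case estimates.
It models drop-out as a thresholded continuous latent **liability** in a
standardized three-variable path model —

```
X  (baseline predictor)
Y = a*X + e_Y                 (follow-up outcome)
L = b*X + c*Y + e_L           (drop-out liability)
```

— and asks how the complete-case mean of `Y` and the OLS slope of `Y` on
`X` behave when only the lowest-liability fraction of the sample is
retained. Because everything is jointly normal, the answers have closed
forms: the retained mean is `-rho_YL * dnorm(t)/pnorm(t)` with
`t = qnorm(retain)`, and the complete-case slope is
`(a - theta*rho_XL*rho_YL) / (1 - theta*rho_XL^2)` where
`theta = 1 - Var(L | L < t)`. A replicated Monte Carlo engine confirms the
closed forms and adds what they cannot give: confidence-interval coverage
and rejection rates at realistic sample sizes.

The package also ships attrition *diagnostics* for real cohort tables
(standardized logistic drop-out regressions with Bonferroni correction,
stayer-versus-dropout correlation comparison, polyserial correlation with
the drop-out indicator) and a synthetic cohort generator with known ground
truth for validating them.

## Worked example

A condition where the outcome strongly drives drop-out (`b = c = .40`)
and half the cohort is lost:

```r
library(attrisim)

m <- path_model(a = .10, b = .40, c = .40)
m
#> Standardized path model (X -> Y -> L)
#>   a (X -> Y): 0.100
#>   b (X -> L): 0.400
#>   c (Y -> L): 0.400
#>   residual variances: Y 0.9900, L 0.6480

rule <- retention_rule(retain = .50)
analytic_retained_mean(m, rule)
#> [1] -0.3510692
analytic_retained_slope(m, rule)
#> [1] -0.02651791
```

The population mean of `Y` is 0 and the population slope is .10; selective
attrition drags the complete-case mean to −.35 and reverses the sign of
the slope. Monte Carlo at the same design (500 replications of n = 1000):

```r
res <- run_condition(m, rule, n = 1000, reps = 500, seed = 1)
round(res[, c("mean_est", "mean_ci_lower", "mean_ci_upper", "mean_coverage",
              "slope_est", "slope_coverage", "slope_reject")], 3)
#>   mean_est mean_ci_lower mean_ci_upper mean_coverage slope_est slope_coverage
#> 1   -0.351        -0.433        -0.269             0    -0.025           20.8
#>   slope_reject
#> 1          7.8
```

No replication's CI covers the true mean, and the slope's CI covers the
true .10 only 20.8% of the time. A full grid over the 15 canonical
dependency patterns and three attrition rates, formatted in the
conventional `estimate (CI) coverage` layout:

```r
grid <- run_grid(a = .10, reps = 500, n = 1000, seed = 1, quiet = TRUE)
writeLines(attr(format_tables(grid, statistic = "mean"), "text"))
#>   y    x      estimate_30%  coverage_30%      estimate_50%  coverage_50%      estimate_70%  coverage_70%
#> .00  .00    .00 (-.07,.08)            96    .00 (-.09,.09)            95    .00 (-.11,.12)            94
#> .10  .00   -.05 (-.13,.02)            71   -.08 (-.17,.01)            55   -.12 (-.23,.00)            47
#> .20  .00  -.10 (-.17,-.02)            25  -.16 (-.25,-.08)           4.6  -.23 (-.34,-.12)           2.8
#> ...
#> .40  .40  -.22 (-.29,-.15)             0  -.35 (-.43,-.27)             0  -.51 (-.62,-.41)             0
```

### Diagnostics on a synthetic cohort with known truth

The generator plants a known education effect on long-term drop-out
(odds ratio 0.59 per SD at 56% attrition) and the diagnostics recover it:

```r
syn <- generate_cohort(cohort_config(), seed = 1)
syn$truth$waves$w15$implied_or
#> education
#>      0.59

cohort <- standardize_predictors(syn$cohort, topp_variable_specs())
attrition_logistic(cohort, "w15", c("education", "finances", "sociability"),
                   n_tests = 16)
#>      variable        or  ci_lower  ci_upper            p separation significant
#> 1   education 0.5701067 0.4935158 0.6585842 2.273543e-14      FALSE        TRUE
#> 2    finances 0.9241760 0.8105770 1.0536953 2.386546e-01      FALSE       FALSE
#> 3 sociability 0.8707158 0.7633865 0.9931352 3.915116e-02      FALSE        TRUE
#>   significant_corrected
#> 1                  TRUE
#> 2                 FALSE
#> 3                 FALSE
```

Education's CI covers the planted 0.59 and survives the Bonferroni
correction; sociability's nominal hit does not (it is a correlated
bystander of the planted effect).

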