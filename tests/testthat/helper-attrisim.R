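# shared fixtures for the test suite; the suite-wide seed is fixed once
SUITE_SEED <- 1L

# the three attrition rates of the default design, as retention fractions
RETAIN_LEVELS <- c(0.70, 0.50, 0.30)

# brute-force oracle for retained-sample moments: one huge cohort, rank
# selection, direct OLS — independent of the analytic truncated-normal path
brute_force_retained <- function(model, retain, n = 1e6, seed = SUITE_SEED) {
  set.seed(seed)
  x <- rnorm(n)
  y <- model$a * x + sqrt(model$resid_var_y) * rnorm(n)
  l <- model$b * x + model$c * y +
    sqrt(model$resid_var_liability) * rnorm(n)
  keep <- order(l)[seq_len(floor(retain * n))]
  xr <- x[keep]
  yr <- y[keep]
  fit <- lm.fit(cbind(1, xr), yr)
  list(mean_y = mean(yr),
       mean_se = sd(yr) / sqrt(length(yr)),
       slope = unname(fit$coefficients[2]),
       slope_se = {
         sxx <- sum((xr - mean(xr))^2)
         sqrt(sum(fit$residuals^2) / (length(xr) - 2) / sxx)
       })
}

# small default-structure synthetic config without the planted waves
null_waves <- function() {
  list(w1 = list(attrition = 0.17, loadings = numeric(0)),
       w15 = list(attrition = 0.56, loadings = numeric(0)))
}
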