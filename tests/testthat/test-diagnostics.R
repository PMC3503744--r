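test_that("skewness screening applies the 2-SE rule", {
  expect_equal(se_skewness(913), 0.0809, tolerance = 5e-4)
  set.seed(SUITE_SEED)
  sym <- maybe_log_transform(rnorm(900, mean = 5))
  expect_false(sym$transformed)
  skew <- maybe_log_transform(rlnorm(900))
  expect_true(skew$transformed)
  expect_gt(skew$skewness, skew$threshold)
  expect_equal(skew$threshold, 2 * se_skewness(900))
  # non-positive values need an explicit shift from the configuration
  bad <- c(rlnorm(500), -0.5)
  expect_error(maybe_log_transform(bad), "shift constant")
  shifted <- maybe_log_transform(bad, shift = 1)
  expect_true(shifted$transformed)
  expect_true(all(is.finite(shifted$values)))
})

test_that("standardization hits flagged continuous variables only", {
  set.seed(SUITE_SEED)
  tab <- data.frame(education = pmin(pmax(rnorm(500, 5.94, 1.45), 1), 8),
                    not_working = rbinom(500, 1, .15),
                    age = rnorm(500, 29.9, 4.77),
                    zscore = rnorm(500))
  specs <- variable_spec(
    name = c("education", "not_working", "age", "zscore"),
    scale = c("continuous", "binary", "continuous", "continuous"),
    standardize = c(TRUE, TRUE, FALSE, TRUE)
  )
  # binary variables are never standardized even if requested
  expect_false(specs$standardize[specs$name == "not_working"])
  out <- standardize_predictors(tab, specs)
  expect_equal(mean(out$education), 0)
  expect_equal(sd(out$education), 1)
  expect_identical(out$not_working, tab$not_working)
  expect_identical(out$age, tab$age)
  expect_equal(out$zscore, scale(tab$zscore)[, 1], tolerance = 1e-12)
  tab$flat <- 1
  expect_error(
    standardize_predictors(tab, variable_spec("flat")), "'flat'")
})

test_that("drop-out regressions recover a planted effect and flag edge cases", {
  cfg <- cohort_config(waves = list(
    w15 = list(attrition = .56,
               loadings = c(education = planted_loading(.59, .56,
                                                        "education")))))
  syn <- generate_cohort(cfg, seed = SUITE_SEED)
  cohort <- standardize_predictors(syn$cohort, topp_variable_specs())
  res <- attrition_logistic(cohort, "w15", "education", n_tests = 16)
  expect_s3_class(res, "attrition_or_result")
  expect_true(res$ci_lower < .59 & .59 < res$ci_upper)
  expect_true(res$ci_lower < res$or & res$or < res$ci_upper)
  expect_equal(attr(res, "alpha_corrected"), 0.003125)
  expect_equal(round(attr(res, "alpha_corrected"), 3), 0.003)
  # adjusted model returns one row per predictor from a joint fit
  adj <- attrition_logistic(cohort, "w15", c("education", "sociability"),
                            adjusted = TRUE, n_tests = 2)
  expect_identical(nrow(adj), 2L)
  expect_true(adj$or[adj$variable == "education"] < 1)
  # no drop-outs at the wave is an error
  cohort$all_in <- 1
  expect_error(attrition_logistic(cohort, "all_in", "education"),
               "no drop-outs")
  # perfect separation is flagged, not fatal
  sep <- data.frame(x = c(-(50:1), 1:50), w = c(rep(1, 50), rep(0, 50)))
  res_sep <- attrition_logistic(sep, "w", "x", n_tests = 1)
  expect_true(res_sep$separation)
  expect_false(res_sep$significant)
})

test_that("an independent predictor triggers at the nominal false-positive rate", {
  set.seed(SUITE_SEED)
  hits <- replicate(300, {
    x <- rnorm(400)
    w <- rbinom(400, 1, .6)
    attrition_logistic(data.frame(x = x, w = w), "w", "x",
                       n_tests = 1)$significant
  })
  rate <- mean(hits)
  expect_lt(abs(rate - .05), 3 * sqrt(.05 * .95 / 300) + .01)
})

test_that("correlation comparison is exact on duplicated groups and sized correctly", {
  set.seed(SUITE_SEED)
  half <- data.frame(hscl = rnorm(120), edu = rnorm(120), str = rnorm(120))
  dup <- rbind(cbind(half, w = 1), cbind(half, w = 0))
  cmp <- compare_baseline_correlations(dup, "hscl", c("edu", "str"), "w")
  expect_equal(cmp$comparisons$r_stayers, cmp$comparisons$r_dropouts)
  expect_equal(cmp$mean_abs_discrepancy, 0)
  expect_identical(cmp$comparisons$n_stayers + cmp$comparisons$n_dropouts,
                   rep(240L, 2))
  tiny <- data.frame(hscl = rnorm(30), edu = rnorm(30),
                     w = c(rep(1, 27), rep(0, 3)))
  expect_warning(res <- compare_baseline_correlations(tiny, "hscl", "edu",
                                                      "w"),
                 "fewer than 10")
  expect_true(is.na(res$mean_abs_discrepancy))
})

test_that("the interaction test holds its type-I error under the null", {
  set.seed(SUITE_SEED)
  p_values <- replicate(2000, {
    y <- rnorm(240)
    x <- .4 * y + rnorm(240)  # same joint distribution in both groups
    g <- rep(c(1, 0), each = 120)
    d <- data.frame(hscl = y, x = x, w = g)
    compare_baseline_correlations(d, "hscl", "x", "w")$
      comparisons$interaction_p
  })
  rate <- 100 * mean(p_values < .05)
  expect_gte(rate, 3.5)
  expect_lte(rate, 6.5)
})

test_that("group-size discrepancy in correlations matches sampling theory", {
  # equal true correlations, groups sized like a 15-year follow-up split
  set.seed(SUITE_SEED)
  disc <- replicate(40, {
    n <- 913
    y <- rnorm(n)
    preds <- vapply(seq_len(15), function(j) {
      rho <- .3
      rho * y + sqrt(1 - rho^2) * rnorm(n)
    }, numeric(n))
    d <- data.frame(hscl = y, preds, w = c(rep(0, 514), rep(1, 399)))
    compare_baseline_correlations(d, "hscl", paste0("X", 1:15),
                                  "w")$mean_abs_discrepancy
  })
  expect_gt(mean(disc), .02)
  expect_lt(mean(disc), .07)
})

test_that("polyserial correlation recovers latent parameters", {
  set.seed(SUITE_SEED)
  # independent pair
  expect_lt(abs(polyserial_corr(rnorm(1000),
                                rbinom(1000, 1, .4))), .1)
  gen <- function(rho, prop_pos, n) {
    z <- rnorm(n)
    w <- rho * z + sqrt(1 - rho^2) * rnorm(n)
    list(x = 3 + 2 * z, d = as.integer(w > qnorm(1 - prop_pos)))
  }
  g1 <- gen(-.30, .56, 913)
  expect_lt(abs(polyserial_corr(g1$x, g1$d) - (-.30)), .06)
  g2 <- gen(.20, .17, 913)
  expect_lt(abs(polyserial_corr(g2$x, g2$d) - .20), .07)
  # two-step estimator bias at cohort size, sociability-style setting
  est <- replicate(300, {
    g <- gen(.20, .17, 913)
    polyserial_corr(g$x, g$d)
  })
  expect_lt(abs(mean(est) - .20), .02)
  expect_error(polyserial_corr(rnorm(100), rep(1, 100)), "single class")
  expect_error(polyserial_corr(rnorm(10), rbinom(10, 1, .5)), "at least 30")
})
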