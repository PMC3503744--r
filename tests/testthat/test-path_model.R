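test_that("path model validates its variance constraints", {
  expect_s3_class(path_model(.10, .40, .40), "path_model")
  expect_error(path_model(1.0, 0, 0), "1 - a\\^2")
  expect_error(path_model(.5, .8, .8), "residual variance")
  # residual variances stored correctly
  m <- path_model(.30, .20, .10)
  expect_equal(m$resid_var_y, 1 - .09)
  expect_equal(m$resid_var_liability, 1 - .04 - .01 - 2 * .3 * .2 * .1)
})

test_that("implied moments follow path tracing and are PSD", {
  cases <- list(
    list(a = .10, b = .00, c = .10, rho_yl = .10, rho_xl = .01),
    list(a = .10, b = .10, c = .10, rho_yl = .11, rho_xl = .11),
    list(a = .30, b = .40, c = .40, rho_yl = .52, rho_xl = .52)
  )
  for (cs in cases) {
    mom <- implied_moments(path_model(cs$a, cs$b, cs$c))
    expect_equal(mom$rho_yl, cs$rho_yl)
    expect_equal(mom$rho_xl, cs$rho_xl)
    expect_equal(mom$rho_xy, cs$a)
    expect_true(isSymmetric(mom$corr))
    expect_equal(unname(diag(mom$corr)), rep(1, 3))
    expect_gte(min(eigen(mom$corr, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
  }
})

test_that("retention rule encodes the design thresholds", {
  r <- retention_rule(0.70, mode = "threshold")
  expect_equal(r$threshold, qnorm(.70))
  expect_equal(round(r$threshold, 2), 0.52)  # ".52 SD above the mean"
  expect_equal(retention_rule(0.30)$threshold, -retention_rule(0.70)$threshold)
  expect_equal(retention_rule(0.50)$attrition, 0.50)
  expect_error(retention_rule(0), "between 0 and 1")
  expect_error(retention_rule(1.2), "between 0 and 1")
})

test_that("analytic retained mean matches its closed form and derived values", {
  expect_equal(analytic_retained_mean(path_model(.1, 0, .1),
                                      retention_rule(.5)),
               .1 * (-dnorm(0) / .5))
  expect_equal(round(analytic_retained_mean(path_model(.1, 0, .1),
                                            retention_rule(.5)), 4),
               -0.0798)
  expect_equal(round(analytic_retained_mean(path_model(.1, 0, .4),
                                            retention_rule(.3)), 4),
               -0.4636)
  # Y independent of L -> no bias, exactly
  expect_identical(analytic_retained_mean(path_model(.25, 0, 0),
                                          retention_rule(.4)), 0)
})

test_that("retained mean is sign-symmetric in c and monotone in |c| and attrition", {
  for (b in c(0, .1, .2)) {
    for (p in RETAIN_LEVELS) {
      rule <- retention_rule(p)
      for (cc in c(.1, .2, .3, .4)) {
        m_pos <- analytic_retained_mean(path_model(.1, b, cc), rule)
        m_neg <- analytic_retained_mean(path_model(.1, b, -cc), rule)
        # negating c negates rho_yl only when b = 0; with b = 0 exact symmetry
        if (b == 0) expect_equal(m_neg, -m_pos)
      }
      biases <- vapply(c(.1, .2, .3, .4), function(cc) {
        abs(analytic_retained_mean(path_model(.1, b, cc), rule))
      }, numeric(1))
      expect_true(all(diff(biases) > 0))
    }
    # higher attrition (lower retention) -> more bias
    by_rate <- vapply(RETAIN_LEVELS, function(p) {
      abs(analytic_retained_mean(path_model(.1, b, .2), retention_rule(p)))
    }, numeric(1))
    expect_true(all(diff(by_rate) > 0))
  }
})

test_that("analytic retained slope agrees with a brute-force simulation oracle", {
  # selection independent of (x, y): slope is exactly a
  expect_equal(analytic_retained_slope(path_model(.23, 0, 0),
                                       retention_rule(.42)), .23)
  cases <- list(
    list(model = path_model(.10, .40, .40), retain = .50, printed = -.03),
    list(model = path_model(.30, .40, .40), retain = .50, printed = .15)
  )
  for (cs in cases) {
    analytic <- analytic_retained_slope(cs$model, retention_rule(cs$retain))
    oracle <- brute_force_retained(cs$model, cs$retain)
    expect_lt(abs(analytic - oracle$slope), 3 * oracle$slope_se)
    expect_lt(abs(analytic - cs$printed), .02)
  }
})

test_that("without predictor dependency the slope is nearly unbiased", {
  for (cc in c(.1, .2, .3, .4)) {
    for (p in c(.7, .5)) {
      slope <- analytic_retained_slope(path_model(.1, 0, cc),
                                       retention_rule(p))
      expect_lt(abs(slope - .1), .02)
    }
  }
})

test_that("beta/odds-ratio mapping behaves and roughly matches the stated values", {
  rule <- retention_rule(.50)
  expect_identical(beta_to_or(0, rule), 1)
  # deterministic population value vs a large simulated fit
  pop <- beta_to_or(.2, rule)
  sim <- beta_to_or(.2, rule, method = "simulate", n_sim = 4e5,
                    seed = SUITE_SEED)
  expect_lt(abs(pop - sim) / pop, .03)
  # the published correspondence is approximate (logistic vs normal
  # threshold); agree within 10%
  stated <- c("0.1" = 1.22, "0.2" = 1.49, "0.3" = 1.82, "0.4" = 2.23)
  for (b in names(stated)) {
    expect_lt(abs(beta_to_or(as.numeric(b), rule) - stated[[b]]) /
                stated[[b]], .10)
  }
  # inverse round-trips
  for (or in c(0.59, 1.45, 2.0)) {
    beta <- or_to_beta(or, rule)
    expect_equal(beta_to_or(beta, rule), or, tolerance = 1e-5)
  }
  expect_identical(or_to_beta(1, rule), 0)
  expect_error(beta_to_or(1.2, rule), "\\|beta\\| < 1")
})
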