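#' Standardized three-variable path model for attrition simulations
#'
#' Defines the population from which cohorts are simulated: a baseline
#' predictor X, a follow-up outcome Y, and a continuous latent liability of
#' dropping out L. All three variables have population mean 0 and variance 1.
#' The structural equations are
#' \deqn{Y = a X + e_Y, \qquad L = b X + c Y + e_L,}
#' with independent normal residuals scaled so that Var(Y) = Var(L) = 1.
#'
#' @param a Standardized path coefficient from the baseline predictor to the
#'   follow-up outcome (the population association of scientific interest).
#' @param b Standardized direct path from the baseline predictor to the
#'   drop-out liability.
#' @param c Standardized direct path from the follow-up outcome to the
#'   drop-out liability.
#'
#' @return An object of class `path_model`: a list with elements `a`, `b`,
#'   `c` and the residual variances `resid_var_y = 1 - a^2` and
#'   `resid_var_liability = 1 - b^2 - c^2 - 2abc`.
#'
#' @details The liability residual variance must be positive, i.e.
#'   `b^2 + c^2 + 2*a*b*c < 1`; this holds throughout the default simulation
#'   grid (`a` in \{.10, .30\}, `b`, `c` in \[0, .40\]).
#'
#' @examples
#' m <- path_model(a = 0.10, b = 0.20, c = 0.30)
#' implied_moments(m)$corr
#' @export
path_model <- function(a, b, c) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (abs(a) >= 1) {
    stop("invalid path model: |a| must be < 1 so that the outcome residual ",
         "variance 1 - a^2 is positive (got a = ", a, ")", call. = FALSE)
  }
  resid_l <- 1 - b^2 - c^2 - 2 * a * b * c
  if (resid_l <= 0) {
    stop("invalid path model: liability residual variance ",
         "1 - b^2 - c^2 - 2abc = ", signif(resid_l, 4),
         " is not positive", call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c,
         resid_var_y = 1 - a^2,
         resid_var_liability = resid_l),
    class = "path_model"
  )
}

#' @export
print.path_model <- function(x, ...) {
  cat("Standardized path model (X -> Y -> L)\n")
  cat(sprintf("  a (X -> Y): %.3f\n  b (X -> L): %.3f\n  c (Y -> L): %.3f\n",
              x$a, x$b, x$c))
  cat(sprintf("  residual variances: Y %.4f, L %.4f\n",
              x$resid_var_y, x$resid_var_liability))
  invisible(x)
}

#' Population moments implied by a path model
#'
#' Path-tracing gives the population correlations among the predictor X,
#' the outcome Y and the drop-out liability L:
#' `rho_xy = a`, `rho_xl = b + a*c` (direct plus indirect via Y), and
#' `rho_yl = c + a*b` (direct plus indirect via X).
#'
#' @param model A [path_model()].
#' @return A list of class `implied_moments` with the 3x3 correlation matrix
#'   `corr` (rows/columns `x`, `y`, `liability`), the individual correlations
#'   `rho_xy`, `rho_xl`, `rho_yl`, and the residual variances of Y and L.
#'   The matrix is checked to be positive semi-definite.
#' @examples
#' implied_moments(path_model(0.10, 0.10, 0.10))
#' @export
implied_moments <- function(model) {
  stopifnot(inherits(model, "path_model"))
  rho_xy <- model$a
  rho_xl <- model$b + model$a * model$c
  rho_yl <- model$c + model$a * model$b
  corr <- matrix(c(1, rho_xy, rho_xl,
                   rho_xy, 1, rho_yl,
                   rho_xl, rho_yl, 1), nrow = 3,
                 dimnames = list(c("x", "y", "liability"),
                                 c("x", "y", "liability")))
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("invalid path model: implied correlation matrix is not positive ",
         "semi-definite (smallest eigenvalue ", signif(min(ev), 4), ")",
         call. = FALSE)
  }
  structure(
    list(corr = corr, rho_xy = rho_xy, rho_xl = rho_xl, rho_yl = rho_yl,
         resid_var_y = model$resid_var_y,
         resid_var_liability = model$resid_var_liability),
    class = "implied_moments"
  )
}

#' Retention rule: which liabilities survive to follow-up
#'
#' Attrition is modelled by selecting completers on the drop-out liability.
#' The rule keeps the fraction `retain` with the lowest liabilities. In the
#' default `"rank"` mode exactly `floor(retain * n)` observations are kept
#' per sample, so the retained n is fixed (e.g. 700/500/300 out of 1000 for
#' 30/50/70 percent attrition). In `"threshold"` mode all observations with
#' liability below the population quantile `qnorm(retain)` are kept, so the
#' retained count varies between samples; with `retain = 0.70` the threshold
#' is about 0.52 standard deviations above the mean.
#'
#' @param retain Retention fraction in (0, 1); the attrition rate is
#'   `1 - retain`.
#' @param mode `"rank"` (default) or `"threshold"`.
#' @return An object of class `retention_rule` with elements `retain`,
#'   `attrition`, `threshold` (= `qnorm(retain)`) and `mode`.
#' @examples
#' retention_rule(0.70)$threshold  # ~0.5244
#' @export
retention_rule <- function(retain = 0.70, mode = c("rank", "threshold")) {
  mode <- match.arg(mode)
  if (!is.numeric(retain) || length(retain) != 1L ||
      !is.finite(retain) || retain <= 0 || retain >= 1) {
    stop("retention fraction must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  structure(
    list(retain = retain, attrition = 1 - retain,
         threshold = stats::qnorm(retain), mode = mode),
    class = "retention_rule"
  )
}

#' @export
print.retention_rule <- function(x, ...) {
  cat(sprintf(
    "Retention rule: keep %.0f%% lowest liabilities (%s mode, threshold %.4f)\n",
    100 * x$retain, x$mode, x$threshold))
  invisible(x)
}

# mean and variance of a standard normal truncated above at t (i.e. of L | L < t)
trunc_mean_below <- function(t) -stats::dnorm(t) / stats::pnorm(t)

trunc_var_below <- function(t) {
  h <- stats::dnorm(t) / stats::pnorm(t)
  1 - t * h - h^2
}

#' Expected complete-case mean of the follow-up outcome
#'
#' Closed-form population value of the retained-sample mean of Y when only
#' observations with liability below the retention quantile are analysed.
#' For a standard bivariate normal (Y, L) with correlation `rho_yl`,
#' \deqn{E[Y \mid L < t] = \rho_{YL} \cdot \left(-\phi(t)/\Phi(t)\right),}
#' where `t = qnorm(retain)`. This is the analytic oracle against which the
#' Monte Carlo mean estimates are checked.
#'
#' @param model A [path_model()].
#' @param rule A [retention_rule()].
#' @return The expected retained-sample mean of the follow-up outcome
#'   (population mean is 0, so this is also the bias).
#' @examples
#' # 50% attrition, weak outcome-liability dependency: bias ~ -0.08
#' analytic_retained_mean(path_model(.10, 0, .10), retention_rule(.50))
#' @export
analytic_retained_mean <- function(model, rule) {
  stopifnot(inherits(model, "path_model"), inherits(rule, "retention_rule"))
  mom <- implied_moments(model)
  mom$rho_yl * trunc_mean_below(rule$threshold)
}

#' Expected complete-case OLS slope of outcome on predictor
#'
#' Closed-form population value of the ordinary least squares slope of Y on X
#' among completers. Truncating a multivariate normal on one coordinate L at
#' `t` transforms the covariance matrix as
#' \deqn{\Sigma^* = \Sigma - \theta\, \sigma_L \sigma_L^\top,
#'   \qquad \theta = 1 - \mathrm{Var}(L \mid L < t),}
#' where \eqn{\sigma_L} is the vector of covariances with L. The expected
#' slope is then `Cov(X, Y | L < t) / Var(X | L < t)`. When `b = 0` and
#' `c = 0` selection is independent of (X, Y) and the slope equals `a`
#' exactly.
#'
#' @inheritParams analytic_retained_mean
#' @return The expected retained-sample OLS slope of Y on X.
#' @examples
#' analytic_retained_slope(path_model(.10, .40, .40), retention_rule(.50))
#' @export
analytic_retained_slope <- function(model, rule) {
  stopifnot(inherits(model, "path_model"), inherits(rule, "retention_rule"))
  mom <- implied_moments(model)
  theta <- 1 - trunc_var_below(rule$threshold)
  cov_xy <- mom$rho_xy - theta * mom$rho_xl * mom$rho_yl
  var_x <- 1 - theta * mom$rho_xl^2
  cov_xy / var_x
}

#' Odds ratio of drop-out per 1-SD of a baseline variable
#'
#' Translates a liability-scale dependency `beta` (the correlation between a
#' standardized baseline variable and the latent drop-out liability) into an
#' odds ratio per 1-SD increase of that variable, as estimated by logistic
#' regression of the observed drop-out indicator (liability above the
#' retention quantile) on the variable.
#'
#' The default `"population"` method computes the large-sample limit of the
#' logistic maximum-likelihood coefficient by fitting a weighted logistic
#' model to the exact conditional drop-out probability
#' `P(drop | z) = 1 - pnorm((tau - beta*z) / sqrt(1 - beta^2))` on a fine
#' normal quadrature grid; it is deterministic. The `"simulate"` method fits
#' an ordinary `glm` to a large simulated sample and converges to the same
#' value. Because a logistic curve only approximates the normal-threshold
#' (probit) process, the mapping is approximate and depends mildly on the
#' attrition rate.
#'
#' @param beta Correlation between the variable and the drop-out liability;
#'   `|beta| < 1`.
#' @param rule A [retention_rule()]; its retention fraction sets the
#'   drop-out prevalence.
#' @param method `"population"` (deterministic quadrature, default) or
#'   `"simulate"`.
#' @param n_sim Sample size for the `"simulate"` method.
#' @param seed Optional seed for the `"simulate"` method.
#' @return The odds ratio (1 when `beta = 0`).
#' @seealso [or_to_beta()] for the inverse mapping.
#' @examples
#' beta_to_or(0.10, retention_rule(0.50))  # ~1.17
#' @export
beta_to_or <- function(beta, rule, method = c("population", "simulate"),
                       n_sim = 2e5, seed = NULL) {
  stopifnot(inherits(rule, "retention_rule"))
  method <- match.arg(method)
  if (!is.numeric(beta) || length(beta) != 1L || abs(beta) >= 1) {
    stop("beta must be a single number with |beta| < 1", call. = FALSE)
  }
  if (beta == 0) return(1)
  tau <- rule$threshold  # drop-out when liability >= qnorm(retain)
  if (method == "population") {
    z <- seq(-8, 8, length.out = 1601L)
    w <- stats::dnorm(z)
    w <- w / sum(w)
    mu <- 1 - stats::pnorm((tau - beta * z) / sqrt(1 - beta^2))
    fit <- suppressWarnings(
      stats::glm(mu ~ z, family = stats::binomial(), weights = w)
    )
    unname(exp(stats::coef(fit)[2L]))
  } else {
    if (!is.null(seed)) set.seed(seed)
    z <- stats::rnorm(n_sim)
    l <- beta * z + sqrt(1 - beta^2) * stats::rnorm(n_sim)
    d <- as.integer(l >= tau)
    fit <- stats::glm.fit(cbind(1, z), d, family = stats::binomial())
    unname(exp(fit$coefficients[2L]))
  }
}

#' Liability-scale dependency implied by a target odds ratio
#'
#' Numerically inverts [beta_to_or()] (population method): finds the
#' correlation `beta` between a standardized baseline variable and the
#' drop-out liability such that logistic regression of drop-out on the
#' variable has the given odds ratio per SD at the rule's attrition rate.
#' Used to plant known effects in synthetic cohorts.
#'
#' @param or Target odds ratio (> 0).
#' @param rule A [retention_rule()].
#' @return The implied `beta` (same sign as `log(or)`).
#' @examples
#' or_to_beta(0.59, retention_rule(0.44))  # education effect at 56% attrition
#' @export
or_to_beta <- function(or, rule) {
  stopifnot(is.numeric(or), length(or) == 1L, or > 0)
  if (or == 1) return(0)
  f <- function(b) log(beta_to_or(b, rule)) - log(or)
  upper <- if (or > 1) 0.995 else 0
  lower <- if (or > 1) 0 else -0.995
  stats::uniroot(f, c(lower, upper), tol = 1e-8)$root
}
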