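#' Simulate one cohort from a path model
#'
#' Draws `n` observations of (x, y, liability) from the standardized
#' population defined by a [path_model()]: `x` standard normal,
#' `y = a*x + e_y`, `liability = b*x + c*y + e_l`, residuals independent
#' normal scaled so all three variables have unit population variance.
#'
#' @param model A [path_model()].
#' @param n Number of observations (>= 10).
#' @param seed Optional integer seed; if supplied the draw is reproducible.
#'   If `NULL` the current RNG state is used (so replicated runs driven by a
#'   single upstream `set.seed()` remain deterministic).
#' @return A `data.frame` with columns `x`, `y`, `liability` and attributes
#'   `model` and `seed`.
#' @examples
#' cohort <- simulate_cohort(path_model(.30, 0, 0), n = 1000, seed = 1)
#' cor(cohort$x, cohort$y)
#' @export
simulate_cohort <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "path_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop("n must be a single number >= 10", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  y <- model$a * x + sqrt(model$resid_var_y) * stats::rnorm(n)
  l <- model$b * x + model$c * y +
    sqrt(model$resid_var_liability) * stats::rnorm(n)
  out <- data.frame(x = x, y = y, liability = l)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Select completers from a simulated cohort
#'
#' Applies a [retention_rule()] to a cohort: in `"rank"` mode the
#' `floor(retain * n)` observations with the lowest liabilities are kept
#' (fixed retained n); in `"threshold"` mode all observations with liability
#' strictly below `qnorm(retain)` are kept (retained n varies by sample).
#' This mimics complete-case analysis / listwise deletion, where only those
#' who remain in a study enter the analysis.
#'
#' @param cohort A data frame with a `liability` column, typically from
#'   [simulate_cohort()].
#' @param rule A [retention_rule()].
#' @return The retained subset of `cohort`, with attributes `rule` and
#'   `n_retained`.
#' @examples
#' cohort <- simulate_cohort(path_model(.10, 0, .20), 1000, seed = 1)
#' nrow(select_completers(cohort, retention_rule(.50)))  # 500
#' @export
select_completers <- function(cohort, rule) {
  stopifnot(is.data.frame(cohort), "liability" %in% names(cohort),
            inherits(rule, "retention_rule"))
  n <- nrow(cohort)
  keep <- if (rule$mode == "rank") {
    m <- floor(rule$retain * n)
    order(cohort$liability)[seq_len(m)]
  } else {
    which(cohort$liability < rule$threshold)
  }
  if (length(keep) < 3L) {
    stop("degenerate sample: fewer than 3 observations retained",
         call. = FALSE)
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "rule") <- rule
  attr(out, "n_retained") <- length(keep)
  out
}

# OLS of y on x plus mean statistics, via direct sums (shared by the user
# API and the Monte Carlo loop). Normal-approximation 95% CIs throughout.
ols_stats <- function(x, y) {
  m <- length(x)
  mean_y <- mean(y)
  se_mean <- stats::sd(y) / sqrt(m)
  mx <- mean(x)
  dx <- x - mx
  sxx <- sum(dx^2)
  if (sxx == 0) {
    stop("singular design: predictor x is constant in the retained sample",
         call. = FALSE)
  }
  slope <- sum(dx * (y - mean_y)) / sxx
  intercept <- mean_y - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  se_slope <- sqrt(rss / (m - 2) / sxx)
  c(m = m, mean_y = mean_y, se_mean = se_mean,
    slope = slope, se_slope = se_slope)
}

#' Complete-case estimates from a retained sample
#'
#' Computes the two quantities the simulation study tracks: the mean of the
#' follow-up outcome `y` (with SE and 95% CI) and the OLS slope of `y` on
#' `x` (with conventional homoskedastic SE, 95% CI, and a two-sided test of
#' zero slope at alpha = .05). CIs are normal-approximation intervals,
#' estimate +/- 1.96 SE; the significance flag is equivalent to the slope CI
#' excluding 0.
#'
#' @param retained A data frame with columns `x` and `y`, typically from
#'   [select_completers()]. Needs at least 3 rows and non-constant `x`.
#' @param rescale_slope If `TRUE`, additionally report the slope
#'   re-standardized by the retained-sample SDs (`slope * sd(x)/sd(y)`).
#'   Default `FALSE`: because population variances are 1, the raw OLS slope
#'   is already on the standardized beta scale.
#' @return A list of class `sample_estimate` with elements `n`, `mean_y`,
#'   `mean_se`, `mean_ci` (length 2), `slope`, `slope_se`, `slope_ci`,
#'   `significant`, and optionally `slope_std`.
#' @examples
#' r <- select_completers(simulate_cohort(path_model(.3, 0, 0), 1000, 1),
#'                        retention_rule(.5))
#' estimate_sample(r)$slope
#' @export
estimate_sample <- function(retained, rescale_slope = FALSE) {
  stopifnot(is.data.frame(retained), all(c("x", "y") %in% names(retained)))
  if (nrow(retained) < 3L) {
    stop("degenerate sample: need at least 3 retained observations",
         call. = FALSE)
  }
  s <- ols_stats(retained$x, retained$y)
  z <- stats::qnorm(0.975)
  out <- list(
    n = unname(s["m"]),
    mean_y = unname(s["mean_y"]),
    mean_se = unname(s["se_mean"]),
    mean_ci = unname(s["mean_y"] + c(-1, 1) * z * s["se_mean"]),
    slope = unname(s["slope"]),
    slope_se = unname(s["se_slope"]),
    slope_ci = unname(s["slope"] + c(-1, 1) * z * s["se_slope"]),
    significant = unname(abs(s["slope"]) > z * s["se_slope"])
  )
  if (rescale_slope) {
    out$slope_std <- out$slope * stats::sd(retained$x) / stats::sd(retained$y)
  }
  class(out) <- "sample_estimate"
  out
}

#' @export
print.sample_estimate <- function(x, ...) {
  cat(sprintf("Complete-case estimates (n = %d)\n", x$n))
  cat(sprintf("  mean of y: %7.4f (95%% CI %.4f, %.4f)\n",
              x$mean_y, x$mean_ci[1], x$mean_ci[2]))
  cat(sprintf("  slope y~x: %7.4f (95%% CI %.4f, %.4f)%s\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Write a cohort (with retention flags) to CSV
#'
#' Debugging helper: dumps a simulated cohort with a `retained` flag column
#' indicating which rows a retention rule would keep.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param rule A [retention_rule()].
#' @param file Path of the CSV file to write.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, rule, file) {
  retained <- rep(0L, nrow(cohort))
  keep <- if (rule$mode == "rank") {
    order(cohort$liability)[seq_len(floor(rule$retain * nrow(cohort)))]
  } else {
    which(cohort$liability < rule$threshold)
  }
  retained[keep] <- 1L
  out <- cbind(cohort, retained = retained)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
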