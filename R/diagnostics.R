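#' Standard error of sample skewness
#'
#' `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` — the normal-theory standard error
#' of the adjusted sample skewness, used in the skewness screening rule.
#'
#' @param n Sample size (> 3).
#' @return The standard error.
#' @examples
#' se_skewness(913)  # ~0.0809
#' @export
se_skewness <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 3)
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Log-transform a variable if it is significantly skewed
#'
#' Screening rule used before correlation and linear regression analyses:
#' a continuous variable is natural-log transformed if and only if its
#' adjusted sample skewness exceeds twice the standard error of skewness
#' ([se_skewness()]). The decision and the quantities behind it are
#' recorded.
#'
#' @param values Numeric vector (missing values ignored for the decision
#'   and preserved in the output).
#' @param shift Constant added before taking logs (default 0). Required to
#'   be set in the analysis configuration when the variable has
#'   non-positive values and the transform triggers.
#' @return A list with `values` (transformed or original), `transformed`
#'   (logical), `skewness`, `se`, `threshold` (= 2 * se) and `shift`.
#' @examples
#' maybe_log_transform(rlnorm(900))$transformed  # TRUE
#' @export
maybe_log_transform <- function(values, shift = 0) {
  stopifnot(is.numeric(values))
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 non-missing values", call. = FALSE)
  skew <- e1071::skewness(values[ok], type = 2)
  se <- se_skewness(n)
  transform <- skew > 2 * se
  out_values <- values
  if (transform) {
    if (any(values[ok] + shift <= 0)) {
      stop("variable is significantly skewed but has non-positive values; ",
           "set a positive shift constant in the analysis configuration ",
           "(smallest value is ", min(values[ok]), ")", call. = FALSE)
    }
    out_values[ok] <- log(values[ok] + shift)
  }
  list(values = out_values, transformed = transform, skewness = skew,
       se = se, threshold = 2 * se, shift = shift)
}

#' Variable specifications for cohort diagnostics
#'
#' Builds the per-variable specification table used by
#' [standardize_predictors()] and the drop-out regressions. Binary variables
#' are never standardized; by default interval-scaled or dichotomous
#' variables such as age, employment status and marital/cohabitation status
#' are also exempt.
#'
#' @param name Character vector of variable names.
#' @param scale `"continuous"` or `"binary"`, recycled.
#' @param standardize Logical, recycled; forced to `FALSE` for binary
#'   variables.
#' @param transform_if_skewed Logical, recycled; whether
#'   [maybe_log_transform()] should be applied.
#' @return A `data.frame` with one row per variable.
#' @export
variable_spec <- function(name, scale = "continuous", standardize = TRUE,
                          transform_if_skewed = FALSE) {
  stopifnot(is.character(name), length(name) >= 1L)
  out <- data.frame(
    name = name,
    scale = rep_len(scale, length(name)),
    standardize = rep_len(standardize, length(name)),
    transform_if_skewed = rep_len(transform_if_skewed, length(name)),
    stringsAsFactors = FALSE
  )
  if (!all(out$scale %in% c("continuous", "binary"))) {
    stop("scale must be 'continuous' or 'binary'", call. = FALSE)
  }
  out$standardize[out$scale == "binary"] <- FALSE
  out
}

#' Standardize continuous predictors of a cohort table
#'
#' Sets flagged continuous predictors to mean 0 and SD 1 (computed on
#' non-missing baseline values) so that odds ratios from the drop-out
#' regressions are comparable effect sizes. Exempt and binary variables are
#' left untouched.
#'
#' @param table A cohort `data.frame`.
#' @param specs A specification table from [variable_spec()].
#' @return The table with flagged columns standardized.
#' @export
standardize_predictors <- function(table, specs) {
  stopifnot(is.data.frame(table), is.data.frame(specs))
  missing_vars <- setdiff(specs$name, names(table))
  if (length(missing_vars)) {
    stop("variables not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(specs))) {
    if (!isTRUE(specs$standardize[i])) next
    v <- table[[specs$name[i]]]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      stop("cannot standardize zero-variance variable '", specs$name[i],
           "'", call. = FALSE)
    }
    table[[specs$name[i]]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  table
}

# single logistic fit -> one result row; flags likely separation instead of
# failing
or_row <- function(formula, data, term, alpha, alpha_corrected) {
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  p <- co[term, "Pr(>|z|)"]
  separation <- !fit$converged || abs(est) > 10 || se > 10
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(
    or = exp(est), ci_lower = exp(est - z * se), ci_upper = exp(est + z * se),
    p = p, separation = separation,
    significant = !separation && p < alpha,
    significant_corrected = !separation && p < alpha_corrected
  )
}

#' Logistic regressions of drop-out on baseline predictors
#'
#' For a given follow-up wave, regresses the drop-out indicator (1 = did not
#' respond at the wave) on baseline predictors: one model per predictor
#' (`adjusted = FALSE`) or all predictors jointly (`adjusted = TRUE`).
#' Predictors are expected to be standardized/transformed beforehand (see
#' [standardize_predictors()], [maybe_log_transform()]) so odds ratios are
#' per 1 SD. Wald 95% CIs on the log-odds scale. A Bonferroni-corrected
#' per-test alpha (`alpha / n_tests`) is reported next to the nominal level;
#' with the default 16 tests at alpha .05 this is .003 (to 3 decimals).
#' Complete cases per analysis; excluded counts are attached.
#'
#' @param table A cohort `data.frame` with a participation flag column for
#'   the wave (1 = responded, 0 = dropped out).
#' @param wave Name of the participation flag column.
#' @param predictors Character vector of predictor column names.
#' @param adjusted Joint model (`TRUE`) or one model per predictor
#'   (`FALSE`, default).
#' @param alpha Nominal significance level (default .05).
#' @param n_tests Number of tests for the Bonferroni correction (default 16,
#'   the standard predictor count of the diagnostics battery).
#' @return A `data.frame` of class `attrition_or_result`, one row per
#'   predictor: `variable`, `or`, `ci_lower`, `ci_upper`, `p`, `separation`,
#'   `significant`, `significant_corrected`, plus attributes
#'   `alpha_corrected`, `adjusted`, `n_used`, `n_dropout`.
#' @export
attrition_logistic <- function(table, wave, predictors, adjusted = FALSE,
                               alpha = 0.05, n_tests = 16) {
  stopifnot(is.data.frame(table), is.character(predictors),
            length(predictors) >= 1L)
  if (!wave %in% names(table)) {
    stop("wave column '", wave, "' not found", call. = FALSE)
  }
  missing_vars <- setdiff(predictors, names(table))
  if (length(missing_vars)) {
    stop("predictors not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  flag <- table[[wave]]
  if (!all(stats::na.omit(flag) %in% c(0, 1))) {
    stop("participation flags must be 0/1", call. = FALSE)
  }
  dropout <- 1 - flag
  if (sum(dropout, na.rm = TRUE) == 0) {
    stop("no drop-outs at wave '", wave, "'", call. = FALSE)
  }
  if (sum(dropout == 0, na.rm = TRUE) == 0) {
    stop("everyone dropped out at wave '", wave, "'", call. = FALSE)
  }
  alpha_corrected <- alpha / n_tests
  dat <- cbind(.dropout = dropout, table[, predictors, drop = FALSE])
  if (adjusted) {
    cc <- stats::complete.cases(dat)
    d <- dat[cc, , drop = FALSE]
    rows <- do.call(rbind, lapply(predictors, function(v) {
      f <- stats::reformulate(predictors, response = ".dropout")
      or_row(f, d, v, alpha, alpha_corrected)
    }))
    n_used <- rep(sum(cc), length(predictors))
  } else {
    rows <- NULL
    n_used <- integer(length(predictors))
    for (k in seq_along(predictors)) {
      v <- predictors[k]
      cc <- stats::complete.cases(dat[, c(".dropout", v)])
      d <- dat[cc, c(".dropout", v), drop = FALSE]
      rows <- rbind(rows, or_row(stats::reformulate(v, ".dropout"), d, v,
                                 alpha, alpha_corrected))
      n_used[k] <- sum(cc)
    }
  }
  out <- cbind(variable = predictors, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "alpha_corrected") <- alpha_corrected
  attr(out, "adjusted") <- adjusted
  attr(out, "n_used") <- n_used
  attr(out, "n_dropout") <- sum(dropout, na.rm = TRUE)
  class(out) <- c("attrition_or_result", class(out))
  out
}

#' Compare baseline correlations between stayers and drop-outs
#'
#' For each predictor, computes the Pearson correlation with a baseline
#' outcome variable separately among those who stayed and those who later
#' dropped out at a wave, and tests equality of the two associations with
#' the interaction term of a linear model
#' `outcome ~ predictor * dropout_group`. The summary statistic is the mean
#' absolute discrepancy between the group-wise correlations.
#'
#' @param table Cohort `data.frame`.
#' @param outcome Name of the continuous baseline outcome variable.
#' @param predictors Character vector of continuous predictor names
#'   (post-transform).
#' @param wave Name of the participation flag column (1 = stayed).
#' @return A list of class `correlation_comparison` with `comparisons` (a
#'   `data.frame`: `variable`, `r_stayers`, `r_dropouts`, `interaction_p`,
#'   `n_stayers`, `n_dropouts`) and `mean_abs_discrepancy`.
#' @export
compare_baseline_correlations <- function(table, outcome, predictors, wave) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            wave %in% names(table))
  group_drop <- table[[wave]] == 0
  if (min(sum(group_drop, na.rm = TRUE),
          sum(!group_drop, na.rm = TRUE)) < 10) {
    warning("a group has fewer than 10 members; comparison skipped")
    return(structure(list(comparisons = NULL,
                          mean_abs_discrepancy = NA_real_),
                     class = "correlation_comparison"))
  }
  rows <- lapply(predictors, function(v) {
    cc <- stats::complete.cases(table[[outcome]], table[[v]], group_drop)
    y <- table[[outcome]][cc]
    x <- table[[v]][cc]
    g <- group_drop[cc]
    fit <- stats::lm(y ~ x * g)
    pint <- summary(fit)$coefficients["x:gTRUE", "Pr(>|t|)"]
    data.frame(variable = v,
               r_stayers = stats::cor(x[!g], y[!g]),
               r_dropouts = stats::cor(x[g], y[g]),
               interaction_p = pint,
               n_stayers = sum(!g), n_dropouts = sum(g))
  })
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  structure(
    list(comparisons = comparisons,
         mean_abs_discrepancy = mean(abs(comparisons$r_stayers -
                                           comparisons$r_dropouts))),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  if (is.null(x$comparisons)) {
    cat("Correlation comparison skipped (group too small)\n")
    return(invisible(x))
  }
  print(x$comparisons, digits = 3)
  cat(sprintf("Mean |r_stayers - r_dropouts|: %.3f\n",
              x$mean_abs_discrepancy))
  invisible(x)
}

#' Polyserial correlation between a continuous variable and a binary indicator
#'
#' Two-step maximum-likelihood polyserial correlation, the latent
#' correlation between a continuous variable and a binary indicator assumed
#' to arise from a thresholded standard normal. Step 1 fixes the threshold
#' at the normal quantile of the observed marginal proportion and the
#' continuous variable's moments at their sample values; step 2 maximizes
#' the conditional likelihood of the indicator given the (standardized)
#' continuous scores over the latent correlation.
#'
#' This is the appropriate estimand for the association between a
#' continuous baseline variable (e.g. educational level) and observed
#' attrition at a wave.
#'
#' @param x Continuous values.
#' @param d Binary indicator (0/1), same length.
#' @return The estimated latent correlation (scalar in (-1, 1)).
#' @examples
#' set.seed(1)
#' z <- rnorm(500); w <- -.3 * z + sqrt(1 - .09) * rnorm(500)
#' polyserial_corr(z, as.integer(w > qnorm(.44)))
#' @export
polyserial_corr <- function(x, d) {
  stopifnot(is.numeric(x), length(x) == length(d))
  ok <- !is.na(x) & !is.na(d)
  x <- x[ok]
  d <- d[ok]
  if (length(x) < 30) stop("need at least 30 observations", call. = FALSE)
  if (!all(d %in% c(0, 1))) stop("indicator must be 0/1", call. = FALSE)
  p1 <- mean(d)
  if (p1 == 0 || p1 == 1) {
    stop("indicator has a single class", call. = FALSE)
  }
  z <- (x - mean(x)) / stats::sd(x)
  tau <- stats::qnorm(1 - p1)  # P(latent > tau) = p1
  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((tau - rho * z) / s)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(d * log(1 - pr) + (1 - d) * log(pr))
  }
  stats::optimize(negll, c(-0.999, 0.999))$minimum
}
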