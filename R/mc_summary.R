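#' Run one replicated attrition condition
#'
#' The Monte Carlo engine: for one cell (path model x retention rule x n x
#' replications) it repeatedly simulates a cohort, applies complete-case
#' selection, computes the per-sample estimates, and aggregates them into
#' the summary statistics reported for each condition — average estimate,
#' aggregated 95% CI, coverage of the population value, and the rejection
#' rate of the zero-slope null. Data generation and analysis are separate
#' steps per replication (external Monte Carlo design).
#'
#' Aggregated CI limits are the means of the per-replication CI limits; the
#' empirical 2.5/97.5 percentile interval of the estimates across
#' replications is also reported (`*_emp_lower/upper`). Coverage for the
#' mean is the percentage of replications whose 95% CI contains the
#' population mean 0; for the slope, the percentage containing the
#' population slope `a`. The rejection rate is the percentage of
#' replications with a two-sided slope test significant at alpha = .05.
#'
#' @param model A [path_model()].
#' @param rule A [retention_rule()].
#' @param n Observations per simulated cohort (default 1000).
#' @param reps Number of replications (default 500, >= 2).
#' @param seed Optional integer seed; the run is deterministic given it.
#' @param max_fail Maximum tolerated fraction of failed replications
#'   (default 0.01); more aborts the condition.
#' @return A one-row `data.frame` of class `condition_summary` with the
#'   condition identifiers (`a`, `b`, `c`, `attrition`, `n`, `reps`,
#'   `seed`), `n_failed`, and the aggregated statistics: `mean_est`,
#'   `mean_ci_lower/upper`, `mean_emp_lower/upper`, `mean_coverage`,
#'   `slope_est`, `slope_ci_lower/upper`, `slope_emp_lower/upper`,
#'   `slope_coverage`, `slope_reject` (percentages in 0–100). The
#'   `*_mc_se` columns carry the Monte Carlo standard error of the average
#'   estimate (SD of the per-replication estimates over `sqrt(reps)`).
#' @examples
#' run_condition(path_model(.10, 0, .10), retention_rule(.50),
#'               n = 1000, reps = 50, seed = 1)
#' @export
run_condition <- function(model, rule, n = 1000, reps = 500, seed = NULL,
                          max_fail = 0.01) {
  stopifnot(inherits(model, "path_model"), inherits(rule, "retention_rule"))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 2) {
    stop("reps must be >= 2", call. = FALSE)
  }
  reps <- as.integer(reps)
  if (!is.null(seed)) set.seed(seed)
  z <- stats::qnorm(0.975)
  est <- matrix(NA_real_, nrow = reps, ncol = 4,
                dimnames = list(NULL, c("mean_y", "se_mean",
                                        "slope", "se_slope")))
  n_failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      cohort <- simulate_cohort(model, n)
      retained <- select_completers(cohort, rule)
      ols_stats(retained$x, retained$y)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      est[r, ] <- res[c("mean_y", "se_mean", "slope", "se_slope")]
    }
  }
  if (n_failed > max_fail * reps) {
    stop("condition aborted: ", n_failed, " of ", reps,
         " replications failed estimation", call. = FALSE)
  }
  if (n_failed > 0L) {
    message(n_failed, " replication(s) failed and were excluded")
    est <- est[stats::complete.cases(est), , drop = FALSE]
  }
  mean_lo <- est[, "mean_y"] - z * est[, "se_mean"]
  mean_hi <- est[, "mean_y"] + z * est[, "se_mean"]
  slope_lo <- est[, "slope"] - z * est[, "se_slope"]
  slope_hi <- est[, "slope"] + z * est[, "se_slope"]
  emp <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))
  mean_emp <- emp(est[, "mean_y"])
  slope_emp <- emp(est[, "slope"])
  out <- data.frame(
    a = model$a, b = model$b, c = model$c,
    retain = rule$retain, attrition = rule$attrition,
    mode = rule$mode, n = n, reps = reps,
    seed = if (is.null(seed)) NA_integer_ else seed,
    n_failed = n_failed,
    mean_est = mean(est[, "mean_y"]),
    mean_mc_se = stats::sd(est[, "mean_y"]) / sqrt(nrow(est)),
    mean_ci_lower = mean(mean_lo), mean_ci_upper = mean(mean_hi),
    mean_emp_lower = mean_emp[1], mean_emp_upper = mean_emp[2],
    mean_coverage = 100 * mean(mean_lo <= 0 & mean_hi >= 0),
    slope_est = mean(est[, "slope"]),
    slope_mc_se = stats::sd(est[, "slope"]) / sqrt(nrow(est)),
    slope_ci_lower = mean(slope_lo), slope_ci_upper = mean(slope_hi),
    slope_emp_lower = slope_emp[1], slope_emp_upper = slope_emp[2],
    slope_coverage = 100 * mean(slope_lo <= model$a & slope_hi >= model$a),
    slope_reject = 100 * mean(abs(est[, "slope"]) > z * est[, "se_slope"])
  )
  class(out) <- c("condition_summary", class(out))
  out
}

#' The default grid of liability dependencies
#'
#' The 15 (c, b) pairs of direct liability dependencies used in the
#' simulation study: the dependency of the drop-out liability on the
#' follow-up outcome (`c`, the "y" dependency) crossed with the dependency
#' on the baseline predictor (`b`, the "x" dependency), with `b <= c`.
#'
#' @return A 15-row `data.frame` with columns `c` and `b`.
#' @export
dependency_grid <- function() {
  data.frame(
    c = c(.00, .10, .20, .30, .40, .10, .20, .30, .40,
          .20, .30, .40, .30, .40, .40),
    b = c(.00, .00, .00, .00, .00, .10, .10, .10, .10,
          .20, .20, .20, .30, .30, .40)
  )
}

#' Deterministic per-cell seed
#'
#' Derives a reproducible per-cell seed from a master seed and a cell
#' index, kept inside 32-bit integer range. Used to give every grid cell,
#' fixture and acceptance condition an independent but fully reproducible
#' random stream.
#'
#' @param master Master integer seed.
#' @param index Cell index (1-based).
#' @return An integer seed.
#' @examples
#' cell_seed(1, 1:3)
#' @export
cell_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647L + 1)
}

#' Run a full grid of attrition conditions
#'
#' Runs [run_condition()] over every combination of dependency pair and
#' attrition rate for a fixed predictor–outcome path `a`. Per-cell seeds are
#' derived deterministically from the master seed and the cell index, so
#' cells are mutually independent and individually reproducible. A failed
#' cell is recorded and the grid continues.
#'
#' @param a Predictor–outcome path coefficient (the population slope).
#' @param pairs Data frame of dependency pairs with columns `c` and `b`
#'   (default [dependency_grid()]).
#' @param rates Attrition rates (default `c(.30, .50, .70)`).
#' @param reps Replications per cell (default 500).
#' @param n Observations per cohort (default 1000).
#' @param seed Master seed (default 1).
#' @param mode Selection mode, `"rank"` or `"threshold"`.
#' @param quiet Suppress the one-line-per-cell progress log.
#' @return A `data.frame` of class `grid_summary`, one row per cell (rows of
#'   failed cells carry `NA` statistics and the error message in `error`).
#' @examples
#' g <- run_grid(a = .10, pairs = dependency_grid()[1:2, ],
#'               rates = .5, reps = 20, seed = 1, quiet = TRUE)
#' @export
run_grid <- function(a, pairs = dependency_grid(), rates = c(.30, .50, .70),
                     reps = 500, n = 1000, seed = 1,
                     mode = c("rank", "threshold"), quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pairs), all(c("c", "b") %in% names(pairs)))
  cells <- expand.grid(pair = seq_len(nrow(pairs)), rate = rates,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- pairs$c[cells$pair[i]]
    bi <- pairs$b[cells$pair[i]]
    rate <- cells$rate[i]
    s <- cell_seed(seed, i)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_condition(path_model(a, bi, ci), retention_rule(1 - rate, mode),
                    n = n, reps = reps, seed = s),
      error = function(e) e
    )
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      row <- data.frame(a = a, b = bi, c = ci, retain = 1 - rate,
                        attrition = rate, mode = mode, n = n, reps = reps,
                        seed = s, n_failed = NA_integer_)
      row[c("mean_est", "mean_mc_se", "mean_ci_lower", "mean_ci_upper",
            "mean_emp_lower", "mean_emp_upper", "mean_coverage",
            "slope_est", "slope_mc_se", "slope_ci_lower", "slope_ci_upper",
            "slope_emp_lower", "slope_emp_upper", "slope_coverage",
            "slope_reject")] <- NA_real_
      row$error <- conditionMessage(res)
      rows[[i]] <- row
      if (!quiet) message(sprintf(
        "cell %2d: c=%.2f b=%.2f attrition=%.0f%% seed=%d FAILED: %s",
        i, ci, bi, 100 * rate, s, conditionMessage(res)))
    } else {
      res$error <- NA_character_
      # store the requested rate/retention exactly (avoids 1 - (1 - rate)
      # floating-point drift in downstream row lookups)
      res$attrition <- rate
      res$retain <- 1 - rate
      rows[[i]] <- res
      if (!quiet) message(sprintf(
        "cell %2d: c=%.2f b=%.2f attrition=%.0f%% seed=%d %.2fs (%d failed reps)",
        i, ci, bi, 100 * rate, s, dt, res$n_failed))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("grid_summary", "data.frame")
  out
}

# "-0.08" -> "-.08"; "-0.00" -> ".00" (sign dropped at zero after rounding)
fmt_est <- function(x) {
  s <- sprintf("%.2f", x)
  s[s == "-0.00"] <- "0.00"
  sub("0\\.", ".", s)
}

# percentages: one decimal below 10, integers otherwise; exact zero bare
fmt_pct <- function(x) {
  ifelse(x == 0, "0",
         ifelse(x < 10, sprintf("%.1f", x), sprintf("%.0f", x)))
}

#' Render grid summaries as publication-style tables
#'
#' Reshapes a [run_grid()] result into the layout of the simulation report
#' tables: one row per dependency pair (`y` = outcome dependency `c`, `x` =
#' predictor dependency `b`), one block of columns per attrition rate.
#' Estimates are rounded to 2 decimals without a leading zero; percentages
#' are printed with one decimal below 10 and as integers otherwise.
#'
#' @param grid A `grid_summary` from [run_grid()].
#' @param statistic `"mean"` (estimated means of the follow-up variable,
#'   with coverage of the population mean) or `"slope"` (estimated
#'   regression coefficients, with coverage and percentage significant).
#' @return A `data.frame` of formatted character columns, with attribute
#'   `"text"` holding aligned plain-text lines.
#' @examples
#' g <- run_grid(.10, dependency_grid()[1:2, ], rates = c(.3, .5),
#'               reps = 20, seed = 1, quiet = TRUE)
#' format_tables(g, "mean")
#' @export
format_tables <- function(grid, statistic = c("mean", "slope")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(grid))
  rates <- sort(unique(grid$attrition))
  pairs <- unique(grid[, c("c", "b")])
  pairs <- pairs[order(match(
    paste(pairs$c, pairs$b),
    paste(dependency_grid()$c, dependency_grid()$b))), , drop = FALSE]
  out <- data.frame(y = fmt_est(pairs$c), x = fmt_est(pairs$b))
  for (rate in rates) {
    blk_est <- character(nrow(pairs))
    blk_cov <- character(nrow(pairs))
    for (j in seq_len(nrow(pairs))) {
      row <- grid[grid$c == pairs$c[j] & grid$b == pairs$b[j] &
                    grid$attrition == rate, ]
      if (nrow(row) != 1L || is.na(row$mean_est)) {
        blk_est[j] <- blk_cov[j] <- "NA"
        next
      }
      if (statistic == "mean") {
        blk_est[j] <- sprintf("%s (%s,%s)", fmt_est(row$mean_est),
                              fmt_est(row$mean_ci_lower),
                              fmt_est(row$mean_ci_upper))
        blk_cov[j] <- fmt_pct(row$mean_coverage)
      } else {
        blk_est[j] <- sprintf("%s (%s,%s)", fmt_est(row$slope_est),
                              fmt_est(row$slope_ci_lower),
                              fmt_est(row$slope_ci_upper))
        blk_cov[j] <- sprintf("%s%% (%s)", fmt_pct(row$slope_coverage),
                              fmt_pct(row$slope_reject))
      }
    }
    lab <- sprintf("%.0f%%", 100 * rate)
    out[[paste0("estimate_", lab)]] <- blk_est
    out[[paste0("coverage_", lab)]] <- blk_cov
  }
  widths <- vapply(out, function(col) max(nchar(c(col))), integer(1))
  widths <- pmax(widths, nchar(names(out)))
  pad <- function(v, w) formatC(v, width = w)
  lines <- paste(mapply(pad, names(out), widths), collapse = "  ")
  for (j in seq_len(nrow(out))) {
    lines <- c(lines, paste(mapply(pad, unlist(out[j, ]), widths),
                            collapse = "  "))
  }
  attr(out, "text") <- lines
  out
}
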