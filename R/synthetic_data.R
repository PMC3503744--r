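#' Baseline variable catalogue of a TOPP-like maternal cohort
#'
#' The default variable catalogue for the synthetic cohort generator: 14
#' continuous baseline variables with the means, SDs and scale bounds of a
#' population-based cohort of N = 913 mothers of 18-month-olds (maternal
#' socio-demographics, psychological distress, temperament, support and
#' stress scales, and child temperament scales), plus two binary indicators
#' (living alone, not working). `outcome_corr` is the target correlation of
#' each variable with the maternal distress score (`hscl`), taken as pooled
#' magnitudes of the observed stayer/drop-out correlations.
#'
#' Binary prevalences are not part of the published descriptives; the
#' defaults (8% living alone, 15% not working) are typical of Norwegian
#' mothers of toddlers in the early 1990s.
#'
#' @return A `data.frame` with columns `name`, `mean`, `sd`, `min`, `max`,
#'   `binary`, `prevalence`, `outcome_corr`.
#' @export
topp_catalogue <- function() {
  data.frame(
    name = c("age", "finances", "education", "hscl", "emotionality",
             "sociability", "activity", "partner_support",
             "support_friends", "chronic_stress", "child_activity",
             "child_sociability", "child_emotionality", "child_shyness",
             "lives_alone", "not_working"),
    mean = c(29.9, 3.58, 5.94, 1.35, 2.53, 3.74, 3.01, 4.45, 4.18, 1.30,
             4.32, 3.95, 2.79, 2.02, NA, NA),
    sd = c(4.77, 0.80, 1.45, 0.34, 0.51, 0.59, 0.70, 0.69, 0.68, 0.31,
           0.55, 0.52, 0.61, 0.63, NA, NA),
    min = c(NA, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, NA, NA),
    max = c(NA, 5, 8, 4, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5, NA, NA),
    binary = c(rep(FALSE, 14), TRUE, TRUE),
    prevalence = c(rep(NA, 14), 0.08, 0.15),
    outcome_corr = c(-0.15, -0.30, -0.17, 1.00, 0.59, -0.18, -0.01,
                     -0.40, -0.32, 0.54, -0.05, 0.01, 0.25, 0.09,
                     0.14, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Attenuation of a standardized score induced by clipping at scale bounds
#'
#' Clipping a normal score at its scale bounds shrinks its correlation with
#' any other variable by the factor `corr(Z, clip(Z))`. The factor is
#' available in closed form from truncated-normal moments and is used to
#' plant marginal drop-out effects on the *observed* (clipped) scale rather
#' than the latent one.
#'
#' @param lower,upper Clipping bounds in standard-score units (may be
#'   infinite).
#' @return The correlation between the unclipped and the clipped score.
#' @examples
#' clip_attenuation(-Inf, 1.42)  # one-sided clipping at +1.42 SD
#' @export
clip_attenuation <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  lo_term <- function(f) if (is.finite(lower)) f(lower) else 0
  hi_term <- function(f) if (is.finite(upper)) f(upper) else 0
  cov_ <- stats::pnorm(upper) - stats::pnorm(lower)
  e1 <- lo_term(function(t) t * stats::pnorm(t)) +
    stats::dnorm(lower) - stats::dnorm(upper) +
    hi_term(function(t) t * (1 - stats::pnorm(t)))
  e2 <- lo_term(function(t) t^2 * stats::pnorm(t)) +
    (cov_ - hi_term(function(t) t * stats::dnorm(t)) +
       lo_term(function(t) t * stats::dnorm(t))) +
    hi_term(function(t) t^2 * (1 - stats::pnorm(t)))
  cov_ / sqrt(e2 - e1^2)
}

#' Clip-attenuation factor for every catalogue variable
#'
#' Applies [clip_attenuation()] to each continuous bounded variable of a
#' catalogue; binary and unbounded variables get factor 1.
#'
#' @param catalogue A variable catalogue (see [topp_catalogue()]).
#' @return A named numeric vector of attenuation factors.
#' @export
catalogue_kappa <- function(catalogue) {
  kap <- rep(1, nrow(catalogue))
  names(kap) <- catalogue$name
  for (j in seq_len(nrow(catalogue))) {
    if (catalogue$binary[j]) next
    lo <- (catalogue$min[j] - catalogue$mean[j]) / catalogue$sd[j]
    hi <- (catalogue$max[j] - catalogue$mean[j]) / catalogue$sd[j]
    if (is.na(lo)) lo <- -Inf
    if (is.na(hi)) hi <- Inf
    if (is.finite(lo) || is.finite(hi)) kap[j] <- clip_attenuation(lo, hi)
  }
  kap
}

#' Liability loading that plants a target odds ratio on the observed scale
#'
#' Solves the latent liability loading such that the *observed* variable —
#' after rescaling to its catalogue mean/SD and clipping at its scale
#' bounds — carries a marginal per-SD drop-out odds ratio equal to `or`.
#' This is [or_to_beta()] divided by the variable's [clip_attenuation()]
#' factor; for unbounded or binary variables the two coincide.
#'
#' @param or Target marginal odds ratio per SD of the observed variable.
#' @param attrition Attrition fraction of the wave.
#' @param variable Catalogue variable name.
#' @param catalogue Variable catalogue (default [topp_catalogue()]).
#' @return The liability loading on the standardized latent score.
#' @examples
#' planted_loading(0.59, 0.56, "education")
#' @export
planted_loading <- function(or, attrition, variable,
                            catalogue = topp_catalogue()) {
  stopifnot(variable %in% catalogue$name)
  rule <- retention_rule(1 - attrition)
  or_to_beta(or, rule) / catalogue_kappa(catalogue)[[variable]]
}

#' Synthetic cohort generator configuration
#'
#' Assembles the configuration for [generate_cohort()]: the variable
#' catalogue, the latent correlation structure, and per-wave attrition with
#' liability loadings. The latent correlations default to a single-factor
#' structure: the outcome variable loads `outcome_loading` on a common
#' distress factor and every other variable loads `outcome_corr /
#' outcome_loading`, which reproduces the catalogue's target
#' variable–outcome correlations exactly and is positive definite by
#' construction. A full correlation matrix can be supplied via `corr` to
#' override it.
#'
#' The default waves plant the two marginal attrition effects the
#' diagnostics are validated against: higher temperamental sociability
#' predicting one-year drop-out (OR 1.45 per SD at 17% attrition) and lower
#' education predicting 15-year drop-out (OR 0.59 per SD at 56% attrition).
#' Loadings are solved from the target odds ratios with [planted_loading()],
#' so the target is carried by the observed clipped variable rather than
#' the latent score.
#'
#' @param n Baseline cohort size (default 913).
#' @param catalogue Variable catalogue (default [topp_catalogue()]).
#' @param outcome Name of the outcome variable in the catalogue (default
#'   `"hscl"`).
#' @param outcome_loading Factor loading of the outcome (default 0.8).
#' @param waves Named list; each element has `attrition` (fraction in
#'   (0, 1)) and `loadings` (named numeric vector of liability loadings on
#'   the standardized latent scale; empty for random attrition). `NULL`
#'   gives the default two waves `w1` and `w15` described above.
#' @param corr Optional full latent correlation matrix (dimnames must match
#'   the catalogue) overriding the single-factor default.
#' @param mode Drop-out selection mode: `"rank"` (exact drop-out counts,
#'   default) or `"threshold"` (binomially varying counts).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 913, catalogue = topp_catalogue(),
                          outcome = "hscl", outcome_loading = 0.8,
                          waves = NULL, corr = NULL,
                          mode = c("rank", "threshold")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(catalogue), outcome %in% catalogue$name,
            n >= 30)
  if (is.null(waves)) {
    waves <- list(
      w1 = list(
        attrition = 0.17,
        loadings = c(sociability = planted_loading(1.45, 0.17, "sociability",
                                                   catalogue))
      ),
      w15 = list(
        attrition = 0.56,
        loadings = c(education = planted_loading(0.59, 0.56, "education",
                                                 catalogue))
      )
    )
  }
  for (w in names(waves)) {
    att <- waves[[w]]$attrition
    if (!is.numeric(att) || att <= 0 || att >= 1) {
      stop("attrition fraction for wave '", w,
           "' must be strictly between 0 and 1", call. = FALSE)
    }
    bad <- setdiff(names(waves[[w]]$loadings), catalogue$name)
    if (length(bad)) {
      stop("unknown variables in loadings for wave '", w, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), catalogue = catalogue, outcome = outcome,
         outcome_loading = outcome_loading, waves = waves, corr = corr,
         mode = mode),
    class = "cohort_config"
  )
}

# latent correlation matrix implied by a config (single-factor default or
# user-supplied); errors on a non-PSD request, reporting the nearest-PSD
# adjustment instead of silently repairing
latent_corr <- function(config) {
  cat_ <- config$catalogue
  p <- nrow(cat_)
  if (!is.null(config$corr)) {
    R <- config$corr
    stopifnot(is.matrix(R), nrow(R) == p,
              identical(rownames(R), cat_$name))
  } else {
    lam <- cat_$outcome_corr / config$outcome_loading
    lam[cat_$name == config$outcome] <- config$outcome_loading
    if (any(abs(lam) > 1)) {
      stop("factor loadings exceed 1; lower outcome_corr or raise ",
           "outcome_loading", call. = FALSE)
    }
    R <- tcrossprod(lam)
    diag(R) <- 1
    dimnames(R) <- list(cat_$name, cat_$name)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    near <- Matrix::nearPD(R, corr = TRUE)
    delta <- max(abs(as.matrix(near$mat) - R))
    stop("requested latent correlation matrix is not positive ",
         "semi-definite (smallest eigenvalue ", signif(min(ev), 4),
         "); the nearest valid correlation matrix differs by up to ",
         signif(delta, 3), " — adjust the configuration accordingly",
         call. = FALSE)
  }
  R
}

#' Generate a synthetic cohort with known attrition ground truth
#'
#' Draws a latent multivariate normal cohort from the configured
#' correlation structure, rescales continuous variables to their catalogue
#' means/SDs and clips them to their printed scale bounds, dichotomizes
#' binary variables at their configured prevalences, and, for each wave,
#' builds a unit-variance drop-out liability as the configured weighted sum
#' of standardized latent scores plus a normal residual. The observations
#' with the highest liabilities are marked as drop-outs (exactly
#' `floor(attrition * n)` of them in `"rank"` mode). The planted parameters
#' are returned alongside the data, so every diagnostic can be checked
#' against known truth.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_cohort` with:
#'   \describe{
#'     \item{`cohort`}{`data.frame`: `id`, one column per catalogue
#'       variable, and one 0/1 participation flag per wave (1 = responded).}
#'     \item{`truth`}{per-wave planted loadings, implied latent
#'       variable–liability correlations (`R %*% w`), implied per-SD odds
#'       ratios of the loaded variables on the observed clipped scale
#'       (latent correlation times the variable's [clip_attenuation()]
#'       factor, mapped through [beta_to_or()]), attrition
#'       fractions and drop-out counts, the latent correlation matrix, the
#'       clipping-induced mean shift per variable, and the seed.}
#'   }
#' @examples
#' syn <- generate_cohort(cohort_config(n = 200, waves = list(
#'   w1 = list(attrition = .2, loadings = c(education = -.3)))), seed = 1)
#' table(syn$cohort$w1)
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  cat_ <- config$catalogue
  n <- config$n
  p <- nrow(cat_)
  R <- latent_corr(config)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
  colnames(Z) <- cat_$name
  cohort <- data.frame(id = seq_len(n))
  clip_shift <- numeric(p)
  names(clip_shift) <- cat_$name
  for (j in seq_len(p)) {
    nm <- cat_$name[j]
    if (cat_$binary[j]) {
      cohort[[nm]] <- as.integer(Z[, j] > stats::qnorm(1 - cat_$prevalence[j]))
    } else {
      v <- cat_$mean[j] + cat_$sd[j] * Z[, j]
      vc <- v
      if (!is.na(cat_$min[j])) vc <- pmax(vc, cat_$min[j])
      if (!is.na(cat_$max[j])) vc <- pmin(vc, cat_$max[j])
      clip_shift[j] <- mean(vc) - mean(v)
      cohort[[nm]] <- vc
    }
  }
  truth_waves <- list()
  for (w in names(config$waves)) {
    wave <- config$waves[[w]]
    wvec <- numeric(p)
    names(wvec) <- cat_$name
    wvec[names(wave$loadings)] <- wave$loadings
    explained <- drop(crossprod(wvec, R %*% wvec))
    if (explained >= 1) {
      stop("liability loadings for wave '", w, "' imply variance >= 1",
           call. = FALSE)
    }
    liability <- drop(Z %*% wvec) + sqrt(1 - explained) * stats::rnorm(n)
    n_drop <- floor(wave$attrition * n)
    dropout <- if (config$mode == "rank") {
      as.integer(rank(liability, ties.method = "first") > n - n_drop)
    } else {
      as.integer(liability > stats::qnorm(1 - wave$attrition))
    }
    cohort[[w]] <- 1L - dropout
    implied <- drop(R %*% wvec)
    names(implied) <- cat_$name
    active <- abs(wvec) > 1e-8
    rule_w <- retention_rule(1 - wave$attrition)
    # per-SD odds ratios on the observed scale: clipping attenuates the
    # variable-liability correlation by the catalogue kappa factor
    kappa <- catalogue_kappa(cat_)
    implied_or <- vapply(kappa[active] * implied[active], beta_to_or,
                         numeric(1), rule = rule_w)
    truth_waves[[w]] <- list(
      attrition = wave$attrition,
      n_dropout = sum(dropout),
      loadings = wave$loadings,
      implied_corr = implied,
      implied_or = implied_or,
      threshold = stats::qnorm(1 - wave$attrition)
    )
  }
  structure(
    list(cohort = cohort,
         truth = list(waves = truth_waves, latent_corr = R,
                      outcome = config$outcome,
                      clip_mean_shift = clip_shift,
                      mode = config$mode, seed = seed)),
    class = "synthetic_cohort"
  )
}

#' Default diagnostic variable specifications for a synthetic cohort
#'
#' Builds the [variable_spec()] table matching [topp_catalogue()]-style
#' cohorts: binary variables and age are not standardized; the
#' right-skewed distress and stressor scores (`hscl`, `chronic_stress`) are
#' screened for log transformation.
#'
#' @param catalogue A variable catalogue (default [topp_catalogue()]).
#' @return A specification `data.frame`.
#' @export
topp_variable_specs <- function(catalogue = topp_catalogue()) {
  variable_spec(
    name = catalogue$name,
    scale = ifelse(catalogue$binary, "binary", "continuous"),
    standardize = !catalogue$binary & catalogue$name != "age",
    transform_if_skewed = catalogue$name %in% c("hscl", "chronic_stress")
  )
}

#' Write a deterministic suite of small cohort fixtures
#'
#' Produces three mini-cohorts (n = 200) for unit testing, with their
#' ground-truth records: a null cohort (attrition independent of every
#' variable), a cohort with the planted education effect on long-term
#' drop-out (target OR 0.59 per SD at 56% attrition), and a cohort with the
#' planted sociability effect on short-term drop-out (target OR 1.45 per SD
#' at 17% attrition). Given the same seed the CSV files are byte-identical
#' across runs.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  null_waves <- list(w1 = list(attrition = 0.17, loadings = numeric(0)),
                     w15 = list(attrition = 0.56, loadings = numeric(0)))
  edu_waves <- list(
    w1 = list(attrition = 0.17, loadings = numeric(0)),
    w15 = list(attrition = 0.56,
               loadings = c(education = planted_loading(0.59, 0.56,
                                                        "education"))))
  soc_waves <- list(
    w1 = list(attrition = 0.17,
              loadings = c(sociability = planted_loading(1.45, 0.17,
                                                         "sociability"))),
    w15 = list(attrition = 0.56, loadings = numeric(0)))
  suite <- list(null = null_waves, planted_education = edu_waves,
                planted_sociability = soc_waves)
  target_or <- list(null = NULL,
                    planted_education = list(w15 = list(education = 0.59)),
                    planted_sociability = list(w1 = list(sociability = 1.45)))
  paths <- list()
  truth_all <- list()
  for (k in seq_along(suite)) {
    nm <- names(suite)[k]
    syn <- generate_cohort(cohort_config(n = 200, waves = suite[[nm]]),
                           seed = cell_seed(seed, k))
    cohort <- syn$cohort
    num <- vapply(cohort, is.double, logical(1))
    cohort[num] <- lapply(cohort[num], round, digits = 5)
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cohort, path, row.names = FALSE)
    paths[[nm]] <- path
    truth <- syn$truth
    truth$target_or <- target_or[[nm]]
    truth$latent_corr <- NULL  # large and reproducible from the config
    # named atomic vectors lose their names in JSON; store them as objects
    truth$waves <- lapply(truth$waves, function(wv) {
      for (f in c("loadings", "implied_corr", "implied_or")) {
        wv[[f]] <- as.list(wv[[f]])
      }
      wv
    })
    truth$clip_mean_shift <- as.list(truth$clip_mean_shift)
    truth_all[[nm]] <- truth
  }
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth_all, truth_path, auto_unbox = TRUE, digits = 10)
  paths$ground_truth <- truth_path
  invisible(paths)
}
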