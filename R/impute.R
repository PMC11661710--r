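#' Iterative forest imputation of missing covariates
#'
#' Fills missing covariate cells before modelling. Missing cells are
#' initialized with the observed mode (factors) or median (numerics), then
#' each incomplete covariate is regressed on the remaining covariates (plus
#' the treatment indicator, which is always complete) with a random forest,
#' and the imputed cells are refreshed; the sweep repeats until the mean
#' normalized change across imputed cells falls below `tol` or `max_iter`
#' sweeps have run. Observed cells are never altered, and outcome fields
#' (`time_months`, `event`) are never imputed nor used as predictors.
#'
#' @param cohort a cohort tibble; `time_months`, `event` and `treatment`
#'   must be complete.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @param max_iter maximum number of sweeps (default 5).
#' @param tol convergence tolerance on the mean normalized change across
#'   imputed cells (default 1e-3).
#' @param covariates covariate columns eligible for imputation and used as
#'   predictors; defaults to [default_covariates()] intersected with the
#'   cohort.
#' @param num_trees trees per imputation forest (default 100).
#' @return a list with `cohort` (imputed) and `report` (tibble: one row per
#'   covariate with `n_missing`, `method`, `iterations`, `delta`).
#' @export
impute_cohort <- function(cohort, seed = 1L, max_iter = 5L, tol = 1e-3,
                          covariates = NULL, num_trees = 100L) {
  validate_cohort(cohort)
  covariates <- covariates %||% intersect(default_covariates(), names(cohort))
  outcome <- c("time_months", "event")
  if (any(outcome %in% covariates)) {
    abort("outcome fields (time_months, event) cannot be imputed")
  }
  if (anyNA(cohort$treatment) || anyNA(cohort$time_months) || anyNA(cohort$event)) {
    abort("treatment and outcome fields must be complete before imputation")
  }

  work <- cohort[, covariates, drop = FALSE]
  # character covariates become factors for forest fitting
  for (cv in covariates) {
    if (is.character(work[[cv]])) work[[cv]] <- factor(work[[cv]])
  }
  work$..Z <- factor(cohort$treatment)

  miss_mask <- lapply(covariates, function(cv) is.na(work[[cv]]))
  names(miss_mask) <- covariates
  n_missing <- vapply(miss_mask, sum, integer(1))
  incomplete <- names(n_missing)[n_missing > 0]

  report <- tibble(variable = covariates, n_missing = as.integer(n_missing),
                   method = NA_character_, iterations = 0L, delta = 0)
  if (length(incomplete) == 0) {
    return(list(cohort = cohort, report = report))
  }

  # high-missingness fallback: mode/median only
  fallback <- incomplete[n_missing[incomplete] / nrow(work) > 0.9]
  if (length(fallback) > 0) {
    warn(paste0("covariate(s) >90% missing, falling back to mode/median: ",
                paste(fallback, collapse = ", ")))
  }
  forest_vars <- setdiff(incomplete, fallback)
  # impute least-missing variables first
  forest_vars <- forest_vars[order(n_missing[forest_vars])]

  mode_of <- function(x) {
    tab <- table(x)
    names(tab)[which.max(tab)]
  }
  # initialize
  for (cv in incomplete) {
    m <- miss_mask[[cv]]
    if (is.factor(work[[cv]])) {
      work[[cv]][m] <- mode_of(work[[cv]][!m])
    } else {
      work[[cv]][m] <- median(work[[cv]][!m], na.rm = TRUE)
    }
    report$method[report$variable == cv] <-
      if (cv %in% fallback) "mode/median" else "forest"
  }

  iters <- 0L
  deltas <- setNames(rep(NA_real_, length(forest_vars)), forest_vars)
  if (length(forest_vars) > 0) {
    for (iter in seq_len(max_iter)) {
      iters <- iter
      for (vi in seq_along(forest_vars)) {
        cv <- forest_vars[[vi]]
        m <- miss_mask[[cv]]
        preds <- setdiff(names(work), cv)
        fit <- ranger::ranger(
          x = work[!m, preds, drop = FALSE], y = work[[cv]][!m],
          num.trees = num_trees,
          seed = seed + 131L * iter + vi,
          respect.unordered.factors = "order",
          num.threads = 1
        )
        new_vals <- predict(fit, data = work[m, preds, drop = FALSE],
                            num.threads = 1,
                            seed = seed + 131L * iter + vi)$predictions
        old_vals <- work[[cv]][m]
        if (is.factor(work[[cv]])) {
          deltas[[cv]] <- mean(as.character(new_vals) != as.character(old_vals))
          work[[cv]][m] <- new_vals
        } else {
          denom <- stats::sd(work[[cv]][!m])
          if (!is.finite(denom) || denom == 0) denom <- 1
          deltas[[cv]] <- sqrt(mean((new_vals - old_vals)^2)) / denom
          work[[cv]][m] <- new_vals
        }
      }
      if (mean(deltas) < tol) break
    }
  }

  out <- cohort
  for (cv in incomplete) {
    v <- work[[cv]]
    if (is.character(cohort[[cv]])) v <- as.character(v)
    if (is.numeric(cohort[[cv]])) v <- as.numeric(v)
    out[[cv]] <- v
  }
  report$iterations[report$variable %in% forest_vars] <- iters
  for (cv in forest_vars) {
    report$delta[report$variable == cv] <- deltas[[cv]]
  }
  list(cohort = out, report = report)
}
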