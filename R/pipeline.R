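#' Pipeline configuration
#'
#' Bundles every stage's parameters so a run can be reproduced from its
#' config snapshot alone. The input is either a cohort tibble or a
#' [generator_config()]; a single seed is fanned out to per-stage seeds by
#' fixed offsets so stages can be re-run in isolation.
#'
#' @param input a cohort tibble or a `generator_config`.
#' @param histology optional filter, `"adenocarcinoma"` or `"squamous"`;
#'   required when the input cohort mixes histologies.
#' @param tau restricted-mean horizon in months (default 120).
#' @param seed global integer seed.
#' @param p_lo,p_hi equipoise band (default 0.1, 0.9).
#' @param ntree,mtry,min_node_deaths,n_cutpoints virtual-twin forest
#'   parameters ([rsf_fit()] defaults).
#' @param propensity_trees trees of the treatment-probability forest.
#' @param impute_max_iter,impute_trees imputation parameters.
#' @param threshold meaningful-benefit cut in months (default 4).
#' @param covariates modelling covariates (default [default_covariates()]).
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   report bundle there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, histology = NULL, tau = 120, seed = 1L,
                            p_lo = 0.1, p_hi = 0.9, ntree = 500L, mtry = NULL,
                            min_node_deaths = 10L, n_cutpoints = 32L,
                            propensity_trees = 500L, impute_max_iter = 5L,
                            impute_trees = 100L, threshold = 4,
                            covariates = NULL, out_dir = NULL) {
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 1)) {
    abort("thresholds must satisfy 0 <= p_lo < p_hi <= 1")
  }
  if (tau <= 0) abort("tau must be positive")
  if (!is.data.frame(input) && !inherits(input, "generator_config")) {
    abort("input must be a cohort tibble or a generator_config")
  }
  structure(list(input = input, histology = histology, tau = tau,
                 seed = as.integer(seed), p_lo = p_lo, p_hi = p_hi,
                 ntree = as.integer(ntree), mtry = mtry,
                 min_node_deaths = as.integer(min_node_deaths),
                 n_cutpoints = as.integer(n_cutpoints),
                 propensity_trees = as.integer(propensity_trees),
                 impute_max_iter = as.integer(impute_max_iter),
                 impute_trees = as.integer(impute_trees),
                 threshold = threshold, covariates = covariates,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the individualized treatment-effect pipeline
#'
#' Executes the four analytic stages end to end on one histology:
#' (1) eligibility — an out-of-bag treatment-probability forest followed by
#' overlap trimming; (2) survival analysis — a random survival forest with
#' treatment-interaction terms on the eligible patients; (3) virtual twins —
#' factual and counterfactual survival curves per patient; (4) lifetime
#' accounting — restricted-mean gain/loss, stratified summaries and benefit
#' classes. Covariate imputation runs before stage 1. Each stage logs its
#' input/output patient counts. With `out_dir` set, writes the report
#' bundle: eligibility audit, twin table, stratum tables (granular and
#' collapsed), follow-up summary, imputation report, counts log and a
#' config snapshot.
#'
#' @param config a `pipeline_config`.
#' @return a `vt_pipeline` list: `eligibility`, `audit`, `imputation`,
#'   `forest_stats`, `twins`, `strata`, `strata_collapsed`, `followup`,
#'   `counts`, `truth` (generator runs only) and the config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- NULL
  if (inherits(config$input, "generator_config")) {
    gen <- generate_cohort(config$input)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    cohort <- config$input
    validate_cohort(cohort)
  }
  if (!is.null(config$histology)) {
    cohort <- dplyr::filter(cohort, .data$histology == !!config$histology)
    if (!is.null(truth)) truth <- dplyr::filter(truth, .data$id %in% cohort$id)
  }
  if (length(unique(cohort$histology)) > 1) {
    abort("cohort mixes histologies; set `histology` or split_by_histology() first")
  }
  counts <- list(input = nrow(cohort))

  imp <- impute_cohort(cohort, seed = seed + 11L,
                       max_iter = config$impute_max_iter,
                       covariates = config$covariates,
                       num_trees = config$impute_trees)
  cohort_imp <- imp$cohort
  counts$imputed <- nrow(cohort_imp)

  p_hat <- fit_treatment_model(cohort_imp, seed = seed + 23L,
                               covariates = config$covariates,
                               num_trees = config$propensity_trees)
  elig <- trim_equipoise(cohort_imp, p_hat, config$p_lo, config$p_hi)
  audit <- audit_strata(elig, cohort_imp)
  eligible <- cohort_imp[elig$patients$eligible, , drop = FALSE]
  counts$eligible <- nrow(eligible)
  if (nrow(eligible) < 2 || length(unique(eligible$treatment)) < 2) {
    abort("equipoise stage left no two-arm eligible cohort to analyze")
  }

  fit <- fit_vt_forest(eligible, covariates = config$covariates,
                       ntree = config$ntree, mtry = config$mtry,
                       min_node_deaths = config$min_node_deaths,
                       n_cutpoints = config$n_cutpoints, seed = seed + 37L)
  twins <- twin_curves(fit, eligible, tau = config$tau)
  counts$twins <- nrow(twins)

  strata <- summarize_strata(twins, threshold = config$threshold)
  strata_collapsed <- summarize_strata(twins, threshold = config$threshold,
                                       collapse_pn = TRUE)
  fup <- followup_summary(eligible$time_months, eligible$event)

  result <- structure(list(
    eligibility = elig, audit = audit, imputation = imp$report,
    forest_stats = glance(fit), twins = twins, strata = strata,
    strata_collapsed = strata_collapsed, followup = fup,
    counts = tibble(stage = names(counts), n = unlist(counts, use.names = FALSE)),
    truth = truth, config = config
  ), class = "vt_pipeline")

  if (!is.null(config$out_dir)) write_pipeline_bundle(result, config$out_dir)
  result
}

write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)
  readr::write_csv(result$eligibility$patients, file.path(dir, "eligibility.csv"))
  readr::write_csv(result$audit, file.path(dir, "eligibility_audit.csv"))
  readr::write_csv(dplyr::select(result$twins, -dplyr::any_of("curves")),
                   file.path(dir, "twins.csv"))
  flat <- function(s) dplyr::mutate(s, outliers = purrr::map_chr(
    .data$outliers, ~ paste(signif(.x, 6), collapse = ";")))
  readr::write_csv(flat(result$strata), file.path(dir, "strata.csv"))
  readr::write_csv(flat(result$strata_collapsed),
                   file.path(dir, "strata_collapsed.csv"))
  readr::write_csv(result$imputation, file.path(dir, "imputation_report.csv"))
  readr::write_csv(result$followup, file.path(dir, "followup.csv"))
  jsonlite::write_json(
    list(counts = result$counts,
         forest = result$forest_stats,
         equipoise = result$eligibility$summary),
    file.path(dir, "log.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  snap <- cfg[setdiff(names(cfg), "input")]
  snap$input <- if (inherits(cfg$input, "generator_config")) {
    c(unclass(cfg$input)[c("n", "histology", "seed")], source = "generator")
  } else {
    list(source = "cohort_table", n = nrow(cfg$input))
  }
  snap$mtry <- snap$mtry %||% NA
  snap$covariates <- snap$covariates %||% default_covariates()
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  p <- plot_gain_loss(result$strata_collapsed)
  suppressMessages(ggplot2::ggsave(file.path(dir, "gain_loss.pdf"), p,
                                   width = 6, height = 6))
  ok <- TRUE
  invisible(dir)
}

#' @export
print.vt_pipeline <- function(x, ...) {
  cat("Virtual-twin pipeline run\n")
  cat("  counts:", paste(x$counts$stage, x$counts$n, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  out-of-bag concordance: %.3f\n", x$forest_stats$oob_concordance))
  cat("  strata:", nrow(x$strata), "pT x pN cells\n")
  invisible(x)
}

#' @export
tidy.vt_pipeline <- function(x, ...) x$strata

#' @export
glance.vt_pipeline <- function(x, ...) {
  tibble(n = x$counts$n[x$counts$stage == "input"],
         n_eligible = x$counts$n[x$counts$stage == "eligible"],
         oob_concordance = x$forest_stats$oob_concordance,
         median_delta = median(x$twins$delta),
         tau = x$config$tau)
}

#' Compare estimates with generator ground truth
#'
#' For a generator-based run, joins the per-patient estimated gain/loss to
#' the closed-form true individual treatment effect and reports: the
#' Spearman correlation between them; a per-stratum sign-agreement table
#' (median estimated delta vs median true effect, for strata with at least
#' `min_n` eligible patients); and the per-stratum bias. Sign agreement is
#' only claimed where the true stratum median is at least `min_effect`
#' months in magnitude; under a null generator no stratum qualifies and the
#' agreement rate is `NA`.
#'
#' @param result a `vt_pipeline` run (or a `twin_result` plus `truth`).
#' @param truth the generator truth tibble; defaults to the one carried by
#'   the run.
#' @param min_n minimum eligible stratum size entering the sign table
#'   (default 20).
#' @param min_effect months; smallest true median magnitude on which a sign
#'   claim is made (default 3).
#' @return a `recovery_report` list: `spearman`, `sign_table` (tibble),
#'   `sign_agreement` (fraction of qualifying strata with matching signs),
#'   `median_bias` (median of estimated minus true effect).
#' @export
validate_recovery <- function(result, truth = NULL, min_n = 20, min_effect = 3) {
  twins <- if (inherits(result, "vt_pipeline")) result$twins else result
  truth <- truth %||% (if (inherits(result, "vt_pipeline")) result$truth else NULL)
  if (is.null(truth)) abort("ground truth is absent; recovery requires a generator-based run")
  tau <- attr(twins, "tau") %||% 120
  tr <- true_ite(truth, tau = tau)
  joined <- dplyr::inner_join(
    tibble(id = twins$id, delta = twins$delta,
           pT = as.character(twins$pT), pN = as.character(twins$pN)),
    tibble(id = tr$id, true_ite = tr$true_ite), by = "id")
  if (nrow(joined) != nrow(twins)) {
    abort("cohort and ground truth do not match: some patients lack truth records")
  }
  sp <- if (stats::sd(joined$true_ite) == 0 || stats::sd(joined$delta) == 0) {
    NA_real_  # undefined under a null (constant) truth
  } else {
    cor(joined$delta, joined$true_ite, method = "spearman")
  }
  sign_table <- joined |>
    dplyr::group_by(.data$pT, .data$pN) |>
    dplyr::summarise(n = dplyr::n(),
                     median_delta = median(.data$delta),
                     median_true = median(.data$true_ite),
                     bias = median(.data$delta - .data$true_ite),
                     .groups = "drop") |>
    dplyr::mutate(qualifies = .data$n >= min_n & abs(.data$median_true) >= min_effect,
                  agree = sign(.data$median_delta) == sign(.data$median_true))
  qual <- dplyr::filter(sign_table, .data$qualifies)
  structure(list(
    spearman = sp,
    sign_table = sign_table,
    sign_agreement = if (nrow(qual) > 0) mean(qual$agree) else NA_real_,
    median_bias = median(joined$delta - joined$true_ite),
    n = nrow(joined)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery vs ground truth (n = %d)\n", x$n))
  cat(sprintf("  Spearman(delta, true ITE): %.3f\n", x$spearman))
  if (is.na(x$sign_agreement)) {
    cat("  sign agreement: no stratum qualifies (null-like truth)\n")
  } else {
    cat(sprintf("  stratum sign agreement: %.0f%%\n", 100 * x$sign_agreement))
  }
  cat(sprintf("  median bias: %.2f months\n", x$median_bias))
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$sign_table

#' @export
glance.recovery_report <- function(x, ...) {
  tibble(spearman = x$spearman, sign_agreement = x$sign_agreement,
         median_bias = x$median_bias, n = x$n)
}
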