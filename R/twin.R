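#' Fit the virtual-twin interaction survival forest
#'
#' Grows a single random survival forest on the eligible, imputed cohort
#' using the treatment-interaction design: all covariate columns, the
#' treatment indicator `Z`, and one `Z:x` interaction column per covariate
#' column (design width `2p + 1`). The interaction columns let trees carve
#' out strata in which the treatment effect differs, which is what the
#' per-patient counterfactual predictions in [twin_curves()] exploit.
#'
#' @param cohort an imputed cohort with both treatment arms present
#'   (typically the equipoise-eligible subset).
#' @param covariates covariate columns (default [default_covariates()]
#'   intersected with the cohort).
#' @param ntree,mtry,min_node_deaths,n_cutpoints,seed forest parameters,
#'   see [rsf_fit()]; the default `min_node_deaths = 10` grows the deeper
#'   trees that treatment-interaction detection needs.
#' @return a `vt_forest`: the `rsf` fit plus the encoded design and cohort
#'   ids.
#' @export
fit_vt_forest <- function(cohort, covariates = NULL, ntree = 500L,
                          mtry = NULL, min_node_deaths = 10L,
                          n_cutpoints = 32L, seed = 1L) {
  validate_cohort(cohort)
  if (length(unique(cohort$treatment)) < 2) {
    abort("both treatment arms must be present to fit the virtual-twin forest")
  }
  design <- encode_design(cohort, interactions = TRUE, covariates = covariates)
  forest <- rsf_fit(design$x, cohort$time_months, cohort$event,
                    ntree = ntree, mtry = mtry,
                    min_node_deaths = min_node_deaths,
                    n_cutpoints = n_cutpoints, seed = seed)
  structure(list(forest = forest, design = design, id = cohort$id),
            class = "vt_forest")
}

#' @export
print.vt_forest <- function(x, ...) {
  cat("Virtual-twin interaction survival forest\n")
  print(x$forest)
  invisible(x)
}

#' @export
glance.vt_forest <- function(x, ...) glance(x$forest)

#' Factual and counterfactual survival curves per patient
#'
#' For each patient, predicts one survival curve under the treatment
#' actually received and one under the counterfactual treatment, obtained
#' by flipping the treatment indicator and recomputing every
#' treatment-interaction column while leaving all covariates untouched.
#' Restricted mean survival under each arm is the area under the
#' corresponding step curve up to `tau`; `delta` is months of restricted
#' lifetime gained (positive) or lost (negative) by adding adjuvant
#' therapy.
#'
#' By default both curves are predicted with out-of-bag trees only: the
#' counterfactual row shares the patient's covariates, so trees grown on
#' the patient pull its prediction toward the factual outcome; scoring both
#' twins on the identical out-of-bag sub-ensemble removes that optimism
#' and cancels shared ensemble noise in the difference.
#' `counterfactual = "all"` instead scores the counterfactual with every
#' tree.
#'
#' @param fit a `vt_forest` from [fit_vt_forest()].
#' @param cohort the cohort the forest was fitted on (same rows, same
#'   order).
#' @param tau horizon in months (default 120, i.e. 10 years).
#' @param counterfactual `"oob"` (default) or `"all"`: trees used for the
#'   counterfactual prediction.
#' @param keep_curves also return the two curve matrices (default `FALSE`).
#' @return a `twin_result` tibble: `id`, `treatment`, `pT`, `pN`,
#'   `rmst_eso`, `rmst_adj`, `delta`, `surv5_eso`, `surv5_adj` (predicted
#'   5-year survival per arm), with attributes `tau` and, if requested,
#'   `curves` (list with `time`, `surv_eso`, `surv_adj`).
#' @export
twin_curves <- function(fit, cohort, tau = 120,
                        counterfactual = c("oob", "all"),
                        keep_curves = FALSE) {
  stopifnot(inherits(fit, "vt_forest"))
  counterfactual <- match.arg(counterfactual)
  if (nrow(cohort) != length(fit$id) || !identical(cohort$id, fit$id)) {
    abort("cohort does not match the rows the virtual-twin forest was fitted on")
  }
  z <- as.numeric(cohort$treatment)
  factual <- predict(fit$forest, fit$design$x, oob = TRUE)
  cf_design <- set_treatment(fit$design, 1 - z)
  counterfactual <- predict(fit$forest, cf_design$x,
                            oob = counterfactual == "oob")

  grid <- factual$time
  s_fact <- factual$surv
  s_cf <- counterfactual$surv
  # route factual/counterfactual to the Eso (Z=0) / Eso+ (Z=1) arms
  s_eso <- s_fact
  s_adj <- s_cf
  treated <- z == 1
  s_eso[treated, ] <- s_cf[treated, ]
  s_adj[treated, ] <- s_fact[treated, ]

  out <- tibble(
    id = cohort$id,
    treatment = cohort$treatment,
    pT = cohort$pT,
    pN = cohort$pN,
    rmst_eso = rmst_matrix(grid, s_eso, tau),
    rmst_adj = rmst_matrix(grid, s_adj, tau),
    surv5_eso = step_eval_matrix(grid, s_eso, 60),
    surv5_adj = step_eval_matrix(grid, s_adj, 60)
  )
  out$delta <- out$rmst_adj - out$rmst_eso
  attr(out, "tau") <- tau
  if (keep_curves) {
    attr(out, "curves") <- list(time = grid, surv_eso = s_eso, surv_adj = s_adj)
  }
  class(out) <- c("twin_result", class(out))
  out
}
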