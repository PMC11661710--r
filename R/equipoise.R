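#' Out-of-bag treatment probability model
#'
#' Fits a probability forest for the treatment indicator on the covariates
#' (no interactions) and returns each patient's out-of-bag probability of
#' receiving adjuvant therapy — each patient is scored only by trees whose
#' bootstrap sample excluded them. These probabilities drive the overlap
#' ("virtual equipoise") trimming in [trim_equipoise()].
#'
#' @param cohort an imputed cohort tibble with both treatment arms present.
#' @param seed integer seed.
#' @param covariates covariate columns (default [default_covariates()]
#'   intersected with the cohort).
#' @param num_trees number of trees (default 500).
#' @param mtry columns tried per split; the default (two thirds of the
#'   columns) grows deliberately sharp trees — overlap trimming needs
#'   resolution in the probability tails, which heavily decorrelated
#'   trees smooth away.
#' @param min_node_size minimum terminal-node size (default 2, same
#'   rationale).
#' @return tibble with `id` and `p_hat` (out-of-bag P(treatment = 1)).
#' @export
fit_treatment_model <- function(cohort, seed = 1L, covariates = NULL,
                                num_trees = 500L, mtry = NULL,
                                min_node_size = 2L) {
  validate_cohort(cohort)
  if (length(unique(cohort$treatment)) < 2) {
    abort("both treatment arms must be present to model treatment probability")
  }
  design <- encode_design(cohort, interactions = FALSE, covariates = covariates)
  if (anyNA(design$x)) {
    abort("covariates contain missing values; impute before fitting the treatment model")
  }
  y <- factor(cohort$treatment, levels = c(0, 1))
  mtry <- mtry %||% ceiling(2 * ncol(design$x) / 3)
  fit <- ranger::ranger(x = as.data.frame(design$x), y = y,
                        probability = TRUE, num.trees = num_trees,
                        mtry = mtry, min.node.size = min_node_size,
                        seed = seed, num.threads = 1)
  p <- fit$predictions[, "1"]
  tibble(id = cohort$id, p_hat = as.numeric(p))
}

#' Overlap ("virtual equipoise") trimming
#'
#' Flags as eligible the patients whose modeled treatment probability lies
#' in `[p_lo, p_hi]` — those with a realistic chance of receiving either
#' strategy under observed practice — and excludes the rest, in both
#' directions (never-treated-like and always-treated-like profiles). The
#' audit summary reports, in the style of clinical-practice checks, the
#' observed treatment rate within the low- and high-probability groups.
#'
#' @param cohort the cohort the probabilities were fitted on.
#' @param p_hat tibble from [fit_treatment_model()] (or a numeric vector in
#'   cohort order).
#' @param p_lo,p_hi eligibility band, `0 <= p_lo < p_hi <= 1`
#'   (default 0.1, 0.9).
#' @return an `equipoise_result` list: `patients` (tibble `id`, `p_hat`,
#'   `treatment`, `eligible`), `summary` (one-row tibble with counts and
#'   low/high-group observed treatment rates) and the thresholds.
#' @export
trim_equipoise <- function(cohort, p_hat, p_lo = 0.1, p_hi = 0.9) {
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 1)) {
    abort("thresholds must satisfy 0 <= p_lo < p_hi <= 1")
  }
  if (is.data.frame(p_hat)) {
    stopifnot(all(c("id", "p_hat") %in% names(p_hat)))
    p <- p_hat$p_hat[match(cohort$id, p_hat$id)]
  } else {
    p <- as.numeric(p_hat)
  }
  if (length(p) != nrow(cohort) || anyNA(p)) {
    abort("p_hat must supply one probability per cohort row")
  }
  patients <- tibble(
    id = cohort$id, p_hat = p, treatment = cohort$treatment,
    eligible = p >= p_lo & p <= p_hi
  )
  low <- dplyr::filter(patients, .data$p_hat < p_lo)
  high <- dplyr::filter(patients, .data$p_hat > p_hi)
  summary <- tibble(
    n = nrow(patients),
    n_eligible = sum(patients$eligible),
    n_excluded = sum(!patients$eligible),
    n_low = nrow(low),
    low_treated = sum(low$treatment),
    low_treated_rate = if (nrow(low) > 0) mean(low$treatment) else NA_real_,
    n_high = nrow(high),
    high_treated = sum(high$treatment),
    high_treated_rate = if (nrow(high) > 0) mean(high$treatment) else NA_real_
  )
  structure(list(patients = patients, summary = summary,
                 p_lo = p_lo, p_hi = p_hi),
            class = "equipoise_result")
}

#' @export
print.equipoise_result <- function(x, ...) {
  s <- x$summary
  cat("Virtual-equipoise trimming (band [", x$p_lo, ", ", x$p_hi, "])\n", sep = "")
  cat("  eligible: ", s$n_eligible, " of ", s$n,
      sprintf(" (%.1f%%)", 100 * s$n_eligible / s$n), "\n", sep = "")
  if (s$n_low > 0) {
    cat(sprintf("  low-probability group: %d of %d (%.2f%%) actually treated\n",
                s$low_treated, s$n_low, 100 * s$low_treated_rate))
  }
  if (s$n_high > 0) {
    cat(sprintf("  high-probability group: %d of %d (%.2f%%) actually treated\n",
                s$high_treated, s$n_high, 100 * s$high_treated_rate))
  }
  invisible(x)
}

#' Stratum-level eligibility audit table
#'
#' Cross-tabulates eligibility and observed treatment by pT x pN stratum,
#' the style of report used to verify that exclusions concentrate where
#' clinical practice was one-sided (early-stage cancers nearly always
#' resected without adjuvant therapy; the most advanced nearly always
#' treated).
#'
#' @param result an `equipoise_result`.
#' @param cohort the matching cohort tibble (needs `pT`, `pN`).
#' @return tibble: `pT`, `pN`, `n`, `n_eligible`, `treated_rate`.
#' @export
audit_strata <- function(result, cohort) {
  stopifnot(inherits(result, "equipoise_result"))
  dplyr::left_join(cohort, result$patients[, c("id", "eligible")], by = "id") |>
    dplyr::group_by(.data$pT, .data$pN) |>
    dplyr::summarise(n = dplyr::n(),
                     n_eligible = sum(.data$eligible),
                     treated_rate = mean(.data$treatment),
                     .groups = "drop")
}

#' @export
tidy.equipoise_result <- function(x, ...) x$patients

#' @export
glance.equipoise_result <- function(x, ...) x$summary
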