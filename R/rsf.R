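#' Fit a random survival forest
#'
#' Grows an ensemble of bootstrap survival trees. Each tree resamples the
#' rows with replacement and recursively splits to maximize the standardized
#' log-rank statistic over `mtry` randomly chosen columns, with candidate
#' cutpoints at midpoints between sorted unique in-node values (at most
#' `n_cutpoints` random candidates per variable). Splitting stops when a
#' node holds fewer than `min_node_deaths` unique death times. Terminal
#' nodes store the Nelson-Aalen cumulative hazard of their in-bag members;
#' the ensemble predicts by averaging terminal cumulative hazards across
#' trees and exponentiating. Ties are handled by the risk-set convention
#' (deaths precede censorings at equal times).
#'
#' Out-of-bag ensemble mortality (the cumulative hazard summed over the
#' event-time grid) yields the stored out-of-bag concordance.
#'
#' @param x numeric design matrix (or data frame coercible to one), no
#'   missing values; typically from [encode_design()].
#' @param time follow-up in months, > 0.
#' @param event death indicator, 0/1; at least one event required.
#' @param ntree number of trees (default 500).
#' @param mtry columns tried per split; default `ceiling(sqrt(p))`.
#' @param min_node_deaths minimum unique death times to attempt a split
#'   (default 15).
#' @param n_cutpoints max random candidate cutpoints per variable
#'   (default 32).
#' @param seed integer seed; growth is deterministic given the seed.
#' @param bootstrap resample rows with replacement (default `TRUE`); with
#'   `FALSE` every tree sees all rows (no out-of-bag predictions exist).
#' @return an object of class `rsf`: trees, in-bag counts, the event-time
#'   grid, parameters, out-of-bag mortality and concordance.
#' @seealso [predict.rsf()], [logrank_statistic()]
#' @export
rsf_fit <- function(x, time, event, ntree = 500L, mtry = NULL,
                    min_node_deaths = 15L, n_cutpoints = 32L, seed = 1L,
                    bootstrap = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("design matrix contains missing values")
  time <- as.numeric(time)
  event <- as.integer(event)
  n <- nrow(x)
  if (length(time) != n || length(event) != n) abort("time/event length mismatch")
  if (sum(event) == 0) abort("all observations censored: no events to split on")
  if (n < 2L * min_node_deaths && n < 2L) abort("too few rows to grow a forest")
  mtry <- mtry %||% ceiling(sqrt(ncol(x)))

  grid <- sort(unique(time[event == 1]))
  evgrid <- rep(-1L, n)
  evgrid[event == 1] <- match(time[event == 1], grid) - 1L

  grown <- .rsf_grow(x, time, event, evgrid, as.integer(ntree),
                     as.integer(mtry), as.integer(min_node_deaths),
                     as.integer(n_cutpoints), as.double(seed), bootstrap)
  fit <- structure(list(
    trees = grown$trees, inbag = grown$inbag, grid = grid,
    n = n, p = ncol(x), colnames = colnames(x),
    ntree = as.integer(ntree), mtry = as.integer(mtry),
    min_node_deaths = as.integer(min_node_deaths),
    n_cutpoints = as.integer(n_cutpoints), seed = as.integer(seed),
    bootstrap = bootstrap, time = time, event = event,
    oob_mortality = NULL, oob_concordance = NA_real_
  ), class = "rsf")

  if (bootstrap && ntree > 1) {
    chf <- .rsf_chf(fit$trees, x, length(grid), fit$inbag, TRUE)
    mortality <- rowSums(chf)
    fit$oob_mortality <- mortality
    ok <- is.finite(mortality)
    cc <- survival::concordance(
      survival::Surv(time[ok], event[ok]) ~ mortality[ok], reverse = TRUE)
    fit$oob_concordance <- as.numeric(cc$concordance)
  }
  fit
}

#' @export
print.rsf <- function(x, ...) {
  cat("Random survival forest: ", x$ntree, " trees, ", x$n, " rows, ",
      x$p, " columns (mtry ", x$mtry, ", min node deaths ",
      x$min_node_deaths, ")\n", sep = "")
  if (is.finite(x$oob_concordance)) {
    cat(sprintf("  out-of-bag concordance: %.3f\n", x$oob_concordance))
  }
  invisible(x)
}

#' @export
glance.rsf <- function(x, ...) {
  tibble(n = x$n, p = x$p, ntree = x$ntree, mtry = x$mtry,
         min_node_deaths = x$min_node_deaths,
         n_events = sum(x$event), oob_concordance = x$oob_concordance)
}

#' Predict survival curves from a random survival forest
#'
#' Ensemble prediction on the cumulative-hazard scale:
#' `S(t) = exp(-Hbar(t))` with `Hbar` the terminal-node Nelson-Aalen
#' cumulative hazard averaged over trees, evaluated on the forest's
#' event-time grid (step interpolation). With `oob = TRUE`, `newdata` must
#' be the training matrix and each row is averaged only over trees whose
#' bootstrap excluded it; a row in-bag in every tree is an error.
#'
#' @param object an `rsf` fit.
#' @param newdata numeric matrix with the training columns.
#' @param oob use out-of-bag trees only (training rows).
#' @param ... unused.
#' @return a `survival_curves` list: `time` (grid) and `surv`
#'   (rows x grid matrix of survival probabilities).
#' @export
predict.rsf <- function(object, newdata, oob = FALSE, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$p) abort("newdata does not match the training design")
  if (oob) {
    if (!object$bootstrap) abort("no out-of-bag trees: forest was grown without bootstrap")
    if (nrow(x) != object$n) {
      abort("oob prediction requires the training rows in training order")
    }
  }
  chf <- .rsf_chf(object$trees, x, length(object$grid), object$inbag, oob)
  bad <- which(!is.finite(chf[, 1]))
  if (length(bad) > 0) {
    abort(paste0("row ", bad[[1]], " is in-bag in every tree; no out-of-bag prediction"))
  }
  structure(list(time = object$grid, surv = exp(-chf), chf = chf),
            class = "survival_curves")
}

#' Tidy survival curves
#'
#' @param x a `survival_curves` object.
#' @param ... unused.
#' @return tibble with `row`, `time`, `surv`.
#' @export
tidy.survival_curves <- function(x, ...) {
  tibble(row = rep(seq_len(nrow(x$surv)), each = length(x$time)),
         time = rep(x$time, nrow(x$surv)),
         surv = as.vector(t(x$surv)))
}

#' Standardized log-rank split statistic
#'
#' The split criterion of the survival trees: over the distinct event times
#' of the pooled node, numerator `sum(dL_i - YL_i * d_i / Y_i)` and variance
#' `sum((YL_i/Y_i) (1 - YL_i/Y_i) ((Y_i - d_i)/(Y_i - 1)) d_i)`, returning
#' `|numerator| / sqrt(variance)`; an uninformative split (zero variance)
#' returns 0.
#'
#' @param time follow-up times.
#' @param event death indicators, 0/1.
#' @param group logical mask: `TRUE` for the left group.
#' @return the standardized statistic (>= 0).
#' @export
logrank_statistic <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  .logrank_stat(as.numeric(time), as.integer(event), as.logical(group))
}

#' Kaplan-Meier and Nelson-Aalen estimates
#'
#' Thin wrappers around [survival::survfit()] returning tidy step
#' functions with the risk-set tie convention (deaths precede censorings).
#'
#' @param time follow-up times.
#' @param event death indicators, 0/1.
#' @return `km_estimate`: tibble `time`, `surv` (product-limit survival at
#'   each distinct event time); `na_estimate`: tibble `time`, `cumhaz`
#'   (Nelson-Aalen cumulative hazard).
#' @export
km_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          stype = 1, ctype = 1)
  keep <- sf$n.event > 0
  tibble(time = sf$time[keep], surv = sf$surv[keep])
}

#' @rdname km_estimate
#' @export
na_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          stype = 2, ctype = 1)
  keep <- sf$n.event > 0
  tibble(time = sf$time[keep], cumhaz = sf$cumhaz[keep])
}

#' Observed and potential follow-up
#'
#' Observed follow-up is summarized among censored patients (those still
#' being followed); potential follow-up — what follow-up would have been
#' had there been no deaths — is the median of the reverse Kaplan-Meier
#' estimator, i.e. Kaplan-Meier with the roles of death and censoring
#' swapped. Also reports the fraction of patients followed beyond the given
#' cutoffs.
#'
#' @param time follow-up in months.
#' @param event death indicators, 0/1.
#' @param cutoffs months; fractions followed beyond each are reported
#'   (default 12, 24, 60).
#' @return one-row tibble: `median_observed`, `median_potential`, and one
#'   `beyond_<k>m` column per cutoff.
#' @export
followup_summary <- function(time, event, cutoffs = c(12, 24, 60)) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  cens <- time[event == 0]
  med_obs <- if (length(cens) > 0) median(cens) else NA_real_
  if (all(event == 1)) {
    med_pot <- NA_real_
  } else if (all(event == 0)) {
    med_pot <- median(time)
  } else {
    rk <- km_estimate(time, 1L - as.integer(event))
    below <- which(rk$surv <= 0.5)
    med_pot <- if (length(below) > 0) rk$time[below[[1]]] else NA_real_
  }
  out <- tibble(median_observed = med_obs, median_potential = med_pot)
  for (k in cutoffs) {
    out[[paste0("beyond_", k, "m")]] <- mean(time > k)
  }
  out
}
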