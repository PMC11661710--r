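#' Restricted mean survival time of a step curve
#'
#' Exact area under a right-continuous survival step function up to the
#' horizon `tau`: the curve is 1 before its first step, takes value
#' `surv[k]` on `[time[k], time[k+1])`, and extends its last value
#' rightward. In months when the grid is in months.
#'
#' @param curve a survival curve: tibble/data frame with `time` and `surv`
#'   columns (or a list with those elements).
#' @param tau horizon, > 0.
#' @return restricted mean survival in the grid's time unit.
#' @export
rmst <- function(curve, tau) {
  if (tau <= 0) abort("tau must be positive")
  rmst_step(curve$time, curve$surv, tau)
}

rmst_step <- function(time, surv, tau) {
  stopifnot(length(time) == length(surv))
  o <- order(time)
  time <- time[o]; surv <- surv[o]
  bounds <- pmin(c(time, Inf), tau)
  area <- min(bounds[[1]], tau) # S = 1 before the first step
  widths <- diff(bounds)
  area + sum(surv * pmax(widths, 0))
}

# vectorized over rows of a survival matrix sharing one grid
rmst_matrix <- function(time, surv, tau) {
  bounds <- pmin(c(time, Inf), tau)
  w <- pmax(diff(bounds), 0)
  as.numeric(min(bounds[[1]], tau) + surv %*% w)
}

# right-continuous step evaluation S(t0) for each row
step_eval_matrix <- function(time, surv, t0) {
  k <- findInterval(t0, time)
  if (k == 0) rep(1, nrow(surv)) else as.numeric(surv[, k])
}

#' Per-patient months gained or lost
#'
#' Extracts the restricted-mean-survival differences from a twin result:
#' positive values are months of restricted lifetime gained by adding
#' adjuvant therapy, negative values months lost. Errors if the twins were
#' computed under different horizons.
#'
#' @param twins a `twin_result` from [twin_curves()], or a list of them.
#' @return tibble `id`, `delta`.
#' @export
gain_loss <- function(twins) {
  if (!is.data.frame(twins) && is.list(twins)) {
    taus <- vapply(twins, function(t) attr(t, "tau"), numeric(1))
    if (length(unique(taus)) > 1) {
      abort("twin results computed under different horizons (tau) cannot be pooled")
    }
    twins <- dplyr::bind_rows(twins)
  }
  tibble(id = twins$id, delta = twins$delta)
}

#' Stratified gain/loss summaries
#'
#' Summarizes months gained or lost per pT x pN cell: quartiles (linear
#' interpolation of order statistics) and 1.5-IQR whiskers of `delta`,
#' outliers beyond the whiskers, mean predicted 5-year survival per arm
#' (percent), and a benefit class — `detriment` when the median is
#' negative, `insignificant benefit` when below `threshold` months, and
#' `meaningful benefit` at or above it. Both the granular pN0-pN3 table and
#' a collapsed pN0 / pN+ table are available.
#'
#' @param twins a `twin_result` tibble.
#' @param threshold months; the meaningful-benefit cut (default 4).
#' @param collapse_pn collapse pN to pN0 vs pN+ (default `FALSE`).
#' @return a `stratum_summary` tibble: `pT`, `pN`, `n`, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `outliers` (list column),
#'   `surv5_eso`, `surv5_adj` (percent), `class`. Empty cells are absent
#'   rows, never zeros.
#' @export
summarize_strata <- function(twins, threshold = 4, collapse_pn = FALSE) {
  if (threshold < 0) abort("threshold must be non-negative")
  d <- tibble(
    pT = as.character(twins$pT),
    pN = as.character(twins$pN),
    delta = twins$delta,
    surv5_eso = twins$surv5_eso,
    surv5_adj = twins$surv5_adj
  )
  if (anyNA(d$pT) || anyNA(d$pN)) {
    abort("every patient must carry pT and pN labels (impute first)")
  }
  if (collapse_pn) {
    d$pN <- ifelse(d$pN == "N0", "N0", "N+")
  }
  out <- d |>
    dplyr::group_by(.data$pT, .data$pN) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = quantile(.data$delta, 0.25, names = FALSE, type = 7),
      median = median(.data$delta),
      q3 = quantile(.data$delta, 0.75, names = FALSE, type = 7),
      surv5_eso = 100 * mean(.data$surv5_eso),
      surv5_adj = 100 * mean(.data$surv5_adj),
      deltas = list(.data$delta),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      whisker_lo = purrr::map2_dbl(.data$deltas, .data$q1 - 1.5 * .data$iqr,
                                   ~ min(.x[.x >= .y])),
      whisker_hi = purrr::map2_dbl(.data$deltas, .data$q3 + 1.5 * .data$iqr,
                                   ~ max(.x[.x <= .y])),
      outliers = purrr::pmap(list(.data$deltas, .data$whisker_lo, .data$whisker_hi),
                             function(x, lo, hi) x[x < lo | x > hi]),
      class = dplyr::case_when(
        .data$median < 0 ~ "detriment",
        .data$median < threshold ~ "insignificant benefit",
        TRUE ~ "meaningful benefit"
      )
    ) |>
    dplyr::select(-"deltas", -"iqr") |>
    dplyr::arrange(.data$pT, .data$pN)
  attr(out, "threshold") <- threshold
  class(out) <- c("stratum_summary", class(out))
  out
}

#' Plot-ready box geometry
#'
#' Converts stratum summaries into box-and-whisker geometry in the style of
#' clinical gain/loss figures: box width proportional to the stratum sample
#' size, whiskers at 1.5 IQR, outliers listed beyond them.
#'
#' @param summaries a `stratum_summary` tibble.
#' @param max_width half-width (x units) of the largest stratum's box
#'   (default 0.4).
#' @return tibble with `pT`, `pN`, `x`, `xmin`, `xmax`, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `width`, `outliers`.
#' @export
boxplot_data <- function(summaries, max_width = 0.4) {
  if (nrow(summaries) == 0) abort("no strata to plot")
  summaries |>
    dplyr::mutate(
      x = as.numeric(factor(.data$pT, levels = pt_levels)),
      width = 2 * max_width * .data$n / max(.data$n),
      xmin = .data$x - .data$width / 2,
      xmax = .data$x + .data$width / 2
    ) |>
    dplyr::select("pT", "pN", "x", "xmin", "xmax", "q1", "median", "q3",
                  "whisker_lo", "whisker_hi", "width", "outliers")
}

#' Gain/loss box-and-whisker plot
#'
#' Draws months of restricted lifetime gained (above zero) or lost (below)
#' per pT category, faceted by pN group, with box width proportional to
#' stratum size — the figure-style view of [summarize_strata()].
#'
#' @param object a `stratum_summary` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stratum_summary <- function(object, ...) {
  bd <- boxplot_data(object)
  pts <- bd |>
    dplyr::select("pT", "pN", "x", "outliers") |>
    tidyr::unnest_longer("outliers", values_to = "delta") |>
    dplyr::filter(!is.na(.data$delta))
  ggplot2::ggplot(bd) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$whisker_lo, yend = .data$whisker_hi)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$q1, ymax = .data$q3),
                       fill = "grey85", colour = "black") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$median, yend = .data$median),
                          linewidth = 1) +
    (if (nrow(pts) > 0)
      ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$delta),
                          size = 0.8)
     else NULL) +
    ggplot2::scale_x_continuous(breaks = seq_along(pt_levels), labels = pt_levels) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pN)) +
    ggplot2::labs(x = "pathologic T category",
                  y = "months of lifetime gained (+) or lost (-) within 10 years") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.stratum_summary
#' @param summaries a `stratum_summary` tibble.
#' @export
plot_gain_loss <- function(summaries, ...) autoplot.stratum_summary(summaries, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
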