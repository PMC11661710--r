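test_that("step-function restricted mean matches rectangles and closed forms", {
  # immortal cohort
  flat <- tibble::tibble(time = c(30, 60), surv = c(1, 1))
  expect_equal(rmst(flat, 120), 120)
  # one-step curve: S = 1 on [0, 60), 0 after
  step <- tibble::tibble(time = 60, surv = 0)
  expect_equal(rmst(step, 120), 60)
  # exponential sampled on a fine grid vs closed form
  for (lam in c(0.005, 0.01, 0.05)) {
    tgrid <- seq(0.1, 120, by = 0.1)
    curve <- tibble::tibble(time = tgrid, surv = exp(-lam * tgrid))
    expect_equal(rmst(curve, 120), rmst_exponential(lam, 120), tolerance = 0.05)
  }
  expect_error(rmst(flat, -1), "positive")
})

test_that("restricted mean is monotone under pointwise dominance", {
  withr::with_seed(23, {
    for (i in 1:20) {
      tgrid <- sort(runif(15, 0, 120))
      s_lo <- sort(runif(15, 0, 1), decreasing = TRUE)
      s_hi <- pmin(s_lo + runif(15, 0, 0.3), 1)
      s_hi <- rev(cummax(rev(s_hi)))   # keep monotone non-increasing
      expect_gte(rmst(list(time = tgrid, surv = s_hi), 100),
                 rmst(list(time = tgrid, surv = s_lo), 100))
    }
  })
})

test_that("gain/loss extraction is sign-symmetric and guards the horizon", {
  tw <- tibble::tibble(id = c("a", "b"), delta = c(2.5, -1))
  attr(tw, "tau") <- 120
  gl <- gain_loss(tw)
  expect_equal(gl$delta, c(2.5, -1))
  tw2 <- tw; attr(tw2, "tau") <- 60
  expect_error(gain_loss(list(tw, tw2)), "tau")

  # swapping the two curves negates the delta
  tgrid <- c(10, 40, 80)
  s1 <- c(0.9, 0.7, 0.4); s0 <- c(0.8, 0.5, 0.2)
  d <- rmst(list(time = tgrid, surv = s1), 120) - rmst(list(time = tgrid, surv = s0), 120)
  d_swap <- rmst(list(time = tgrid, surv = s0), 120) - rmst(list(time = tgrid, surv = s1), 120)
  expect_equal(d_swap, -d)
  expect_gt(d, 0)  # uniformly higher curve gains lifetime
})

make_twins <- function(deltas, pt = "T2", pn = "N0") {
  tw <- tibble::tibble(
    id = as.character(seq_along(deltas)),
    treatment = rep_len(c(0L, 1L), length(deltas)),
    pT = factor(pt, levels = survtwin:::pt_levels, ordered = TRUE),
    pN = factor(pn, levels = survtwin:::pn_levels, ordered = TRUE),
    rmst_eso = 60, rmst_adj = 60 + deltas,
    surv5_eso = 0.5, surv5_adj = 0.55, delta = deltas
  )
  attr(tw, "tau") <- 120
  class(tw) <- c("twin_result", class(tw))
  tw
}

test_that("stratum summaries classify benefit from the median delta", {
  s0 <- summarize_strata(make_twins(c(-2, -1, 0, 1, 2)))
  expect_equal(s0$median, 0)
  expect_equal(s0$class, "insignificant benefit")

  s_neg <- summarize_strata(make_twins(c(-13, -11, -8)))
  expect_equal(s_neg$median, -11)
  expect_equal(s_neg$class, "detriment")

  s_pos <- summarize_strata(make_twins(c(7.9, 8.2, 9.0)), threshold = 4)
  expect_equal(s_pos$median, 8.2)
  expect_equal(s_pos$class, "meaningful benefit")
})

test_that("stratum table partitions the cohort and collapses pN correctly", {
  tw <- dplyr::bind_rows(
    make_twins(rnorm(40), "T3", "N0"),
    make_twins(rnorm(25), "T3", "N2"),
    make_twins(rnorm(10), "T4", "N3")
  )
  attr(tw, "tau") <- 120
  s <- summarize_strata(tw)
  expect_equal(sum(s$n), 75)
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  sc <- summarize_strata(tw, collapse_pn = TRUE)
  expect_setequal(sc$pN, c("N0", "N+"))
  expect_equal(sum(sc$n), 75)
  # whiskers stay inside the data range
  expect_true(all(s$whisker_lo >= vapply(split(tw$delta, paste(tw$pT, tw$pN)), min, 1)[
    paste(s$pT, s$pN)]))
})

test_that("box geometry is width-proportional and outliers match a recount", {
  tw <- dplyr::bind_rows(make_twins(rnorm(100, 0, 3), "T2", "N1"),
                         make_twins(rnorm(50, 2, 3), "T3", "N1"))
  attr(tw, "tau") <- 120
  s <- summarize_strata(tw)
  bd <- boxplot_data(s)
  w <- bd$width[match(c("T2", "T3"), bd$pT)]
  expect_equal(w[1] / w[2], 2)

  # brute-force outlier recount per cell
  for (k in seq_len(nrow(s))) {
    cell <- tw$delta[tw$pT == s$pT[k] & tw$pN == s$pN[k]]
    q <- quantile(cell, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    expected <- sum(cell < q[1] - 1.5 * iqr | cell > q[2] + 1.5 * iqr)
    expect_length(s$outliers[[k]], expected)
  }

  # degenerate all-equal stratum: zero-height box, no outliers
  s_flat <- summarize_strata(make_twins(rep(1.5, 12)))
  expect_equal(s_flat$q1, s_flat$q3)
  expect_length(s_flat$outliers[[1]], 0)
  expect_s3_class(plot_gain_loss(s_flat), "ggplot")
})
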