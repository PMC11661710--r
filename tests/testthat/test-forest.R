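test_that("log-rank statistic matches the brute-force risk-set oracle", {
  # symmetric groups with identical outcomes -> 0
  tm <- c(1, 2, 3, 1, 2, 3)
  ev <- c(1, 1, 0, 1, 1, 0)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(logrank_statistic(tm, ev, grp), 0)

  # fully specified small case against the oracle
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); grp <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(logrank_statistic(tm, ev, grp), brute_logrank(tm, ev, grp))

  # single event total
  tm <- c(5, 7, 9, 11); ev <- c(0, 1, 0, 0); grp <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(logrank_statistic(tm, ev, grp), brute_logrank(tm, ev, grp))

  # randomized instances with ties
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(3:25, 1)
      tm <- sample(1:8, n, replace = TRUE)
      ev <- rbinom(n, 1, 0.7)
      grp <- as.logical(rbinom(n, 1, 0.5))
      if (sum(ev) == 0 || all(grp) || !any(grp)) next
      expect_equal(logrank_statistic(tm, ev, grp), brute_logrank(tm, ev, grp),
                   tolerance = 1e-12)
    }
  })
})

test_that("split finder equals exhaustive brute-force maximization", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(8:25, 1)
      p <- sample(1:3, 1)
      x <- matrix(sample(1:6, n * p, replace = TRUE), n, p)
      tm <- sample(1:10, n, replace = TRUE)
      ev <- rbinom(n, 1, 0.8)
      if (sum(ev) == 0) next
      got <- survtwin:::.rsf_best_split(x, as.numeric(tm), as.integer(ev))
      expect_equal(got$stat, brute_best_split(x, tm, ev), tolerance = 1e-12)
    }
  })
})

test_that("a single root-node tree reproduces the pooled Nelson-Aalen survival", {
  tm <- c(2, 4, 4, 7)
  ev <- c(1, 1, 0, 1)
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  fit <- rsf_fit(x, tm, ev, ntree = 1, min_node_deaths = 100, seed = 1,
                 bootstrap = FALSE)
  pred <- predict(fit, x)
  # hand-tabulated: H = 1/4 at t=2, 1/4+1/3 at t=4, 1/4+1/3+1 at t=7
  expect_equal(pred$time, c(2, 4, 7))
  expect_equal(pred$chf[1, ], c(1/4, 1/4 + 1/3, 1/4 + 1/3 + 1))
  expect_equal(pred$surv[1, ], exp(-c(1/4, 1/4 + 1/3, 1/4 + 1/3 + 1)))
  # every row gets the same (pooled) curve
  expect_true(all(apply(pred$surv, 2, function(col) length(unique(col)) == 1)))
  # matches the hand-looped Nelson-Aalen oracle
  ora <- brute_nelson_aalen(tm, ev)
  expect_equal(pred$chf[1, ], ora$cumhaz)
})

test_that("forest contracts hold: monotone curves, no early hazard, determinism", {
  withr::with_seed(30, {
    n <- 150
    x <- cbind(a = rnorm(n), b = rnorm(n))
    tm <- 6 + rexp(n, 0.05)   # no events before month 6
    ev <- rbinom(n, 1, 0.8)
  })
  fit <- rsf_fit(x, tm, ev, ntree = 30, seed = 4)
  pred <- predict(fit, x)
  expect_true(all(pred$surv >= 0 & pred$surv <= 1))
  expect_true(all(apply(pred$surv, 1, function(s) all(diff(s) <= 1e-12))))
  expect_true(min(pred$time) >= 6)

  fit2 <- rsf_fit(x, tm, ev, ntree = 30, seed = 4)
  expect_identical(predict(fit2, x)$surv, pred$surv)

  expect_error(rsf_fit(x, tm, rep(0L, n)), "censored")
})

test_that("forest predictions average over trees (order invariance)", {
  withr::with_seed(8, {
    n <- 120
    x <- cbind(a = rnorm(n), b = runif(n))
    tm <- rexp(n, 0.04 * exp(0.8 * (x[, 1] > 0)))
    ev <- rbinom(n, 1, 0.9)
  })
  fit <- rsf_fit(x, tm, ev, ntree = 20, seed = 2)
  full <- predict(fit, x)$chf
  # averaging the two half-ensembles reproduces the full ensemble
  h1 <- fit; h1$trees <- fit$trees[1:10]; h1$inbag <- fit$inbag[, 1:10]
  h2 <- fit; h2$trees <- fit$trees[11:20]; h2$inbag <- fit$inbag[, 11:20]
  half_avg <- (predict(h1, x)$chf + predict(h2, x)$chf) / 2
  expect_equal(half_avg, full, tolerance = 1e-12)
})

test_that("out-of-bag concordance rises with real prognostic signal", {
  withr::with_seed(14, {
    n <- 600
    x <- cbind(g = rbinom(n, 1, 0.5), noise = rnorm(n))
    tm <- rexp(n, 0.03 * 3^x[, "g"])
    cens <- runif(n, 5, 80)
    ev <- as.integer(tm <= cens)
    tm <- pmin(tm, cens)
  })
  fit <- rsf_fit(x, tm, ev, ntree = 100, seed = 6)
  expect_gt(fit$oob_concordance, 0.6)
})

test_that("km and Nelson-Aalen wrappers agree with hand calculations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # all censored -> survival identically 1 (no event rows in the step table)
  km2 <- km_estimate(c(4, 9), c(0, 0))
  expect_equal(nrow(km2), 0)

  na <- na_estimate(c(2, 4, 4, 7), c(1, 1, 0, 1))
  expect_equal(na$cumhaz, c(1/4, 1/4 + 1/3, 1/4 + 1/3 + 1))
  # KM and exp(-NA) agree to O(sum (d/Y)^2) on small data
  km3 <- km_estimate(c(2, 4, 4, 7), c(1, 1, 0, 1))
  expect_true(all(abs(km3$surv - exp(-na$cumhaz)) <=
                    cumsum(c(1/4, 1/3, 1)^2)))
})

test_that("follow-up summary: reverse Kaplan-Meier potential follow-up", {
  # hand-computed toy: censorings at 24 and 36 are reverse-KM events;
  # reverse-KM survival drops to 1/2 at t = 24 -> median potential 24
  fs <- followup_summary(c(12, 24, 36), c(1, 0, 0))
  expect_equal(fs$median_potential, 24)
  expect_equal(fs$median_observed, 30)

  # no deaths: potential follow-up is the empirical median
  fs2 <- followup_summary(c(10, 20, 30), c(0, 0, 0))
  expect_equal(fs2$median_potential, 20)

  # mortality-heavy cohort: potential >= observed follow-up
  g <- generate_cohort(paper_like_preset("adenocarcinoma", n = 2000, seed = 17))
  fs3 <- followup_summary(g$cohort$time_months, g$cohort$event)
  expect_gte(fs3$median_potential, fs3$median_observed)
  expect_true(fs3$beyond_12m >= fs3$beyond_24m)
})
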