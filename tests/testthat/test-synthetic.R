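test_that("generation is bit-identical under the same seed", {
  cfg <- paper_like_preset("adenocarcinoma", n = 300, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth, g2$truth)
})

test_that("null effect map gives exactly zero true effects", {
  cfg <- paper_like_preset("adenocarcinoma", n = 200, seed = 3, null_effect = TRUE)
  tr <- true_ite(generate_cohort(cfg)$truth, tau = 120)
  expect_true(all(tr$true_ite == 0))
})

test_that("closed-form true effects match direct evaluation and limits", {
  # frozen from the closed form (1 - exp(-lambda tau)) / lambda
  expect_equal(rmst_exponential(0.01, 120), (1 - exp(-1.2)) / 0.01)
  truth <- tibble::tibble(id = "x", lambda_eso = 0.02, lambda_adj = 0.01)
  expect_equal(true_ite(truth, tau = 120)$true_ite, 24.41646, tolerance = 1e-6)
  # equal arms -> 0
  truth2 <- tibble::tibble(id = "y", lambda_eso = 0.02, lambda_adj = 0.02)
  expect_equal(true_ite(truth2, tau = 120)$true_ite, 0)
  # vanishing horizon -> 0
  expect_lt(abs(true_ite(truth, tau = 1e-6)$true_ite), 1e-9)
  expect_error(rmst_exponential(-0.01, 120), "positive")
})

test_that("saturated assignment logit is deterministic in the extreme strata", {
  cfg <- paper_like_preset("adenocarcinoma", n = 2000, seed = 9)
  cfg$assign_coef <- c(a0 = -200, aT = 50, aN = 50, aM = 0)
  g <- generate_cohort(cfg)
  pt <- g$truth$pT
  pn <- g$truth$pN
  z <- g$cohort$treatment
  t4n3 <- pt == "T4" & pn == "N3"
  t1n0 <- pt == "T1" & pn == "N0"
  expect_true(all(z[t4n3] == 1))
  expect_true(all(z[t1n0] == 0))
})

test_that("treatment assignment is confounded with depth of invasion", {
  g <- generate_cohort(paper_like_preset("adenocarcinoma", n = 4000, seed = 1))
  z <- g$cohort$treatment
  pt <- g$truth$pT
  expect_gt(mean(z[pt == "T4"]) - mean(z[pt == "T1"]), 0.3)
})

test_that("single-stratum untreated survival matches its exponential law", {
  # degenerate config: everyone Tis N0 M0 R0-ish, never treated
  cfg <- paper_like_preset("adenocarcinoma", n = 5000, seed = 21)
  cfg$pt_probs <- c(1, 0, 0, 0, 0)
  cfg$pn_given_pt <- matrix(rep(c(1, 0, 0, 0), 5), nrow = 5, byrow = TRUE)
  cfg$assign_coef <- c(a0 = -200, aT = 0, aN = 0, aM = 0)
  cfg$censor_window <- c(500, 501)   # effectively uncensored on [0, 130]
  cfg$missing_rates <- c(pT = 0, pN = 0)
  g <- generate_cohort(cfg)
  km <- km_estimate(g$cohort$time_months, g$cohort$event)
  lam <- g$truth$lambda_eso
  # per-patient hazards differ (age, margin, comorbidity); compare to the
  # population-average survival curve by Monte Carlo over the known hazards
  keep <- km$time <= 120
  s_true <- vapply(km$time[keep], function(t) mean(exp(-lam * t)), numeric(1))
  expect_lt(max(abs(km$surv[keep] - s_true)), 0.05)
})

test_that("stratum-median true effects of the presets sit in the clinical range", {
  g <- generate_cohort(paper_like_preset("adenocarcinoma", n = 20000, seed = 2))
  tr <- true_ite(g$truth, tau = 120)
  med <- tapply(tr$true_ite, list(as.character(tr$pT), as.character(tr$pN)), median)
  # benefit confined to the T4 row and N3 column
  expect_gt(med["T4", "N0"], 4)
  expect_lt(med["T4", "N0"], 10)
  expect_true(all(med["T4", ] > 3))
  expect_true(all(med[c("T1", "T2", "T3"), "N3"] > 3))
  # detriment in node-negative shallow disease
  expect_true(all(med[c("T1", "T2", "T3"), "N0"] < -3))
  # no-effect belt
  expect_true(all(abs(med[c("T1", "T2", "T3"), c("N1", "N2")]) < 1))

  gs <- generate_cohort(paper_like_preset("squamous", n = 20000, seed = 2))
  trs <- true_ite(gs$truth, tau = 120)
  meds <- tapply(trs$true_ite, list(as.character(trs$pT), as.character(trs$pN)), median)
  expect_true(all(meds[c("T3", "T4"), "N0"] > 3))
  expect_true(all(meds[c("T2", "T3", "T4"), c("N1", "N2", "N3")] > 3))
  expect_lt(meds["T1", "N0"], -3)
})

test_that("invalid generator configs fail before any draw", {
  cfg <- paper_like_preset("adenocarcinoma", n = 100)
  bad <- cfg; bad$pt_probs <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(generate_cohort(bad), "summing to 1")
  bad <- cfg; bad$censor_window <- c(10, 5)
  expect_error(generate_cohort(bad), "cmax")
  bad <- cfg; bad$effect_map <- cfg$effect_map[1:4, ]
  expect_error(generate_cohort(bad), "5x4")
})
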