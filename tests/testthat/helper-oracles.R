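# Independent oracles used to freeze expected values. Deliberately written
# differently from the package implementation (explicit risk-set loops).

# Brute-force standardized log-rank statistic: tabulate risk sets time by
# time with loops over the pooled sample.
brute_logrank <- function(time, event, left) {
  ts <- sort(unique(time[event == 1]))
  num <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    Y <- sum(at_risk)
    YL <- sum(at_risk & left)
    d <- sum(time == t & event == 1)
    dL <- sum(time == t & event == 1 & left)
    num <- num + dL - YL * d / Y
    if (Y > 1) {
      v <- v + (YL / Y) * (1 - YL / Y) * ((Y - d) / (Y - 1)) * d
    }
  }
  if (v <= 0) return(0)
  abs(num) / sqrt(v)
}

# Exhaustive best log-rank split over all columns and midpoint cutpoints.
brute_best_split <- function(x, time, event) {
  best <- 0
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (cut in (u[-1] + u[-length(u)]) / 2) {
      left <- x[, j] <= cut
      if (all(left) || !any(left)) next
      s <- brute_logrank(time, event, left)
      if (s > best) best <- s
    }
  }
  best
}

# Nelson-Aalen cumulative hazard by hand (deaths precede censorings at ties).
brute_nelson_aalen <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  H <- numeric(length(ts))
  acc <- 0
  for (i in seq_along(ts)) {
    Y <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    acc <- acc + d / Y
    H[i] <- acc
  }
  list(time = ts, cumhaz = H)
}

# A tiny hand-buildable cohort tibble for schema-level tests.
toy_cohort <- function(n = 8, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("T%02d", seq_len(n)),
      histology = rep(c("adenocarcinoma", "squamous"), length.out = n),
      age = round(runif(n, 45, 80)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      pT = factor(sample(c("T1", "T2", "T3"), n, replace = TRUE),
                  levels = c("Tis", "T1", "T2", "T3", "T4"), ordered = TRUE),
      pN = factor(sample(c("N0", "N1"), n, replace = TRUE),
                  levels = c("N0", "N1", "N2", "N3"), ordered = TRUE),
      pM = factor("M0", levels = c("M0", "M1"), ordered = TRUE),
      margin = factor("R0", levels = c("R0", "R1", "R2"), ordered = TRUE),
      grade = sample(1:3, n, replace = TRUE),
      comorbidity_count = rpois(n, 1),
      weight_loss = rbinom(n, 1, 0.3),
      location = sample(c("lower", "middle"), n, replace = TRUE),
      treatment = rep(c(0L, 1L), length.out = n),
      time_months = round(runif(n, 2, 90), 1),
      event = rbinom(n, 1, 0.7)
    )
  })
}
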