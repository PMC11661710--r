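test_that("cohort CSV round-trips typed values, mapping X to missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,histology,age,sex,pT,pN,pM,margin,treatment,time_months,event",
    "a,adenocarcinoma,61,M,3,X,M0,R0,0,14.5,1",
    "b,squamous,70,F,X,1,M1,R1,1,30,0",
    "c,adenocarcinoma,55,M,1,N2,M0,R2,1,8.25,1"
  ), path)
  ch <- read_cohort(path)
  expect_equal(stage_rank(ch$pT), c(3L, NA, 1L))
  expect_equal(stage_rank(ch$pN), c(NA, 1L, 2L))
  expect_equal(as.character(ch$margin), c("R0", "R1", "R2"))
  expect_equal(ch$time_months, c(14.5, 30, 8.25))

  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, out)
  back <- read_cohort(out)
  expect_equal(back$pT, ch$pT)
  expect_equal(back$pN, ch$pN)
  expect_equal(back$time_months, ch$time_months)
  expect_equal(back$event, ch$event)
})

test_that("degenerate and invalid cohort files are rejected with clear errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_cohort(empty), "empty|read")

  nohead <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,histology,age", nohead)
  expect_error(read_cohort(nohead), "mandatory")

  bad_event <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,histology,treatment,time_months,event",
    "a,adenocarcinoma,0,12,1",
    "b,adenocarcinoma,1,20,2"
  ), bad_event)
  expect_error(read_cohort(bad_event), "event.*row 2")
})

test_that("design encoding is definitional: ranks, interactions, flipping", {
  ch <- toy_cohort(6)
  d0 <- encode_design(ch, interactions = FALSE, covariates = c("pT", "age"))
  expect_identical(colnames(d0$x), c("pT", "age"))
  expect_equal(d0$x[, "pT"], as.numeric(stage_rank(ch$pT)))

  d1 <- encode_design(ch, interactions = TRUE, covariates = c("pT", "age"))
  expect_identical(colnames(d1$x), c("pT", "age", "Z", "Z:pT", "Z:age"))
  # interaction-off design is a column subset of interaction-on
  expect_equal(d1$x[, colnames(d0$x)], d0$x)
  # Z = 0 rows have all-zero interaction entries
  z0 <- ch$treatment == 0
  expect_true(all(d1$x[z0, c("Z", "Z:pT", "Z:age")] == 0))
  # flipping Z changes exactly the Z-derived columns
  flipped <- set_treatment(d1, 1 - ch$treatment)
  same <- c("pT", "age")
  expect_equal(flipped$x[, same], d1$x[, same])
  expect_equal(flipped$x[, "Z"], 1 - d1$x[, "Z"])
  expect_equal(flipped$x[, "Z:age"], (1 - ch$treatment) * ch$age)
  # flipping twice is the identity
  expect_equal(set_treatment(flipped, ch$treatment)$x, d1$x)
})

test_that("interactions on a cohort with missing staging is a precondition error", {
  ch <- toy_cohort(6)
  ch$pT[2] <- NA
  expect_error(encode_design(ch, interactions = TRUE, covariates = c("pT", "age")),
               "impute")
})

test_that("histology split partitions any cohort", {
  ch <- toy_cohort(11)
  parts <- split_by_histology(ch)
  expect_equal(nrow(parts$adenocarcinoma) + nrow(parts$squamous), nrow(ch))
  expect_length(intersect(parts$adenocarcinoma$id, parts$squamous$id), 0)

  all_ac <- dplyr::mutate(ch, histology = "adenocarcinoma")
  parts2 <- split_by_histology(all_ac)
  expect_equal(nrow(parts2$adenocarcinoma), nrow(ch))
  expect_equal(nrow(parts2$squamous), 0)
})

test_that("ordinal staging codes preserve category order", {
  pt <- factor(c("Tis", "T1", "T2", "T3", "T4"),
               levels = c("Tis", "T1", "T2", "T3", "T4"), ordered = TRUE)
  expect_equal(stage_rank(pt), 0:4)
  expect_true(all(diff(stage_rank(pt)) > 0))
})
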