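#' Pathologic staging categories
#'
#' Ordered category levels for pathologic tumor depth (pT), nodal involvement
#' (pN), distant metastasis (pM) and resection margin used throughout the
#' package. `Tis` (in-situ) is the shallowest pT category and is ranked below
#' `T1`; `TX`/`NX` ("cannot be assessed") carry no rank and are represented as
#' missing values.
#'
#' @name staging_levels
NULL

pt_levels <- c("Tis", "T1", "T2", "T3", "T4")
pn_levels <- c("N0", "N1", "N2", "N3")
pm_levels <- c("M0", "M1")
margin_levels <- c("R0", "R1", "R2")

histology_levels <- c("adenocarcinoma", "squamous")

#' Ordinal rank of a staging factor
#'
#' Maps ordered staging categories to integer ranks used by the design
#' matrix: Tis = 0 < T1 = 1 < ... < T4 = 4, N0 = 0 < ... < N3 = 3,
#' M0 = 0 / M1 = 1, R0 = 0 < R1 = 1 < R2 = 2. Missing (X) categories map
#' to `NA`.
#'
#' @param x an ordered staging factor (`pT`, `pN`, `pM` or `margin`).
#' @return integer ranks, `NA` where the category is missing.
#' @export
stage_rank <- function(x) {
  as.integer(x) - 1L
}

stage_factor <- function(rank, levels) {
  factor(levels[rank + 1L], levels = levels, ordered = TRUE)
}

#' Default modelling covariates
#'
#' The covariates used by the equipoise and virtual-twin forests when none
#' are supplied: staging (`pT`, `pN`, `pM`, `margin`) plus demographic and
#' tumor descriptors (`age`, `sex`, `grade`, `comorbidity_count`,
#' `weight_loss`, `location`). A stand-in for a fuller registry covariate
#' list; any columns of the cohort table can be declared instead.
#'
#' @return character vector of column names.
#' @export
default_covariates <- function() {
  c("pT", "pN", "pM", "margin", "age", "sex", "grade",
    "comorbidity_count", "weight_loss", "location")
}
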