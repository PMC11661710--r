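#' Read a patient cohort table
#'
#' Reads a rectangular cohort CSV (one row per patient) into a typed tibble.
#' Staging columns are parsed to ordered factors; the strings `"X"`, `"TX"`,
#' `"NX"` and empty cells become missing values destined for imputation.
#' Unparseable cells in optional covariates are recorded as missing with a
#' message; violations of the outcome/treatment domain are errors.
#'
#' Required columns: `id`, `histology`, `treatment`, `time_months`, `event`.
#' Staging columns (`pT`, `pN`, `pM`, `margin`) and any free covariate
#' columns are carried along when present.
#'
#' @param path path to a CSV file with a header row.
#' @param covariates optional character vector naming the covariate columns
#'   to retain (defaults to every non-mandatory column present).
#' @return a cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, covariates = NULL) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE),
    error = function(e) abort(paste0("cannot read cohort file: ", conditionMessage(e)))
  )
  if (ncol(raw) == 0) {
    abort("cohort file is empty: no header")
  }
  mandatory <- c("id", "histology", "treatment", "time_months", "event")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    abort("cohort file is empty: no patient rows")
  }
  if (!is.null(covariates)) {
    keep <- union(mandatory, intersect(names(raw), covariates))
    raw <- raw[, keep, drop = FALSE]
  }
  parse_stage <- function(x, levels, prefix) {
    x <- trimws(x)
    x[x %in% c("", "X", paste0(prefix, "X"), "NA")] <- NA_character_
    bare <- !is.na(x) & !startsWith(x, substr(levels[[2]], 1, 1)) & x != "Tis"
    # allow bare numeric codes ("3" -> "T3"/"N3"/"R2" style)
    num <- suppressWarnings(as.integer(x))
    lev <- x
    lev[bare & !is.na(num)] <- levels[match(num[bare & !is.na(num)],
                                            stage_rank(factor(levels, levels = levels, ordered = TRUE)))]
    bad <- !is.na(lev) & !(lev %in% levels)
    if (any(bad)) {
      inform(paste0(sum(bad), " unparseable ", prefix, " cell(s) recorded as missing"))
      lev[bad] <- NA_character_
    }
    factor(lev, levels = levels, ordered = TRUE)
  }
  out <- raw
  n_unparse <- 0L
  if ("pT" %in% names(out)) out$pT <- parse_stage(out$pT, pt_levels, "T")
  if ("pN" %in% names(out)) out$pN <- parse_stage(out$pN, pn_levels, "N")
  if ("pM" %in% names(out)) out$pM <- parse_stage(out$pM, pm_levels, "M")
  if ("margin" %in% names(out)) out$margin <- parse_stage(out$margin, margin_levels, "R")

  to_num <- function(x, name) {
    x[trimws(x) == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is.na(x)
    if (any(bad)) {
      n_unparse <<- n_unparse + sum(bad)
      v[bad] <- NA_real_
    }
    v
  }
  for (col in setdiff(names(out), c("id", "histology", "pT", "pN", "pM", "margin",
                                    "sex", "location"))) {
    out[[col]] <- to_num(out[[col]], col)
  }
  if (n_unparse > 0) inform(paste0(n_unparse, " unparseable numeric cell(s) recorded as missing"))
  out$treatment <- as.integer(out$treatment)
  out$event <- as.integer(out$event)
  out <- as_tibble(out)
  validate_cohort(out)
  out
}

#' Validate a cohort tibble
#'
#' Checks the contracts every downstream stage relies on: `time_months > 0`,
#' `event` and `treatment` binary, `histology` never missing. Errors name
#' the first offending row.
#'
#' @param cohort a cohort tibble.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  req <- c("id", "histology", "treatment", "time_months", "event")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort lacks mandatory column(s): ", paste(miss, collapse = ", ")))
  }
  check_domain <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(paste0("invalid ", what, " at row ", bad[[1]],
                   if (length(bad) > 1) paste0(" (and ", length(bad) - 1L, " more)")))
    }
  }
  check_domain(!is.na(cohort$event) & cohort$event %in% c(0L, 1L), "event (must be 0/1)")
  check_domain(!is.na(cohort$treatment) & cohort$treatment %in% c(0L, 1L),
               "treatment (must be 0/1)")
  check_domain(!is.na(cohort$time_months) & cohort$time_months > 0,
               "time_months (must be > 0)")
  check_domain(!is.na(cohort$histology), "histology (must not be missing)")
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: staging factors are written as their category
#' labels and missing cells as empty strings, so that reading the file back
#' reproduces the typed values.
#'
#' @param cohort a cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in intersect(c("pT", "pN", "pM", "margin"), names(out))) {
    out[[col]] <- as.character(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Split a cohort by histopathologic cell type
#'
#' The analysis is run separately per histology; this partitions the cohort
#' into adenocarcinoma and squamous cell carcinoma sub-cohorts.
#'
#' @param cohort a cohort tibble.
#' @return a named list with elements `adenocarcinoma` and `squamous`.
#' @export
split_by_histology <- function(cohort) {
  validate_cohort(cohort)
  list(
    adenocarcinoma = dplyr::filter(cohort, .data$histology == "adenocarcinoma"),
    squamous = dplyr::filter(cohort, .data$histology == "squamous")
  )
}

#' Encode a cohort as a numeric design matrix
#'
#' Ordinal staging factors are coded by rank (Tis = 0 below T1), binary
#' covariates as 0/1, nominal covariates one-hot, numeric covariates as-is.
#' With `interactions = TRUE` the treatment indicator `Z` and one `Z:x`
#' product column per covariate column are appended, which is the design the
#' virtual-twin forest is grown on; the returned column metadata records
#' which columns derive from `Z` so the treatment can be flipped
#' consistently by [set_treatment()].
#'
#' @param cohort a cohort tibble.
#' @param interactions append treatment and treatment-interaction columns?
#'   Requires a fully imputed cohort (no missing covariate values).
#' @param covariates covariate column names; defaults to the intersection of
#'   [default_covariates()] with the cohort's columns.
#' @return a list with `x` (numeric matrix) and `info` (tibble with one row
#'   per column: `column`, `role` in covariate/treatment/interaction, and
#'   `base`, the covariate column an interaction multiplies).
#' @export
encode_design <- function(cohort, interactions = FALSE, covariates = NULL) {
  covariates <- covariates %||% intersect(default_covariates(), names(cohort))
  cols <- list()
  for (cv in covariates) {
    x <- cohort[[cv]]
    if (is.null(x)) abort(paste0("covariate not in cohort: ", cv))
    if (is.ordered(x)) {
      cols[[cv]] <- as.numeric(stage_rank(x))
    } else if (is.factor(x) || is.character(x)) {
      x <- as.factor(x)
      if (nlevels(x) <= 2) {
        cols[[cv]] <- as.numeric(x == levels(x)[nlevels(x)])
      } else {
        for (lv in levels(x)) {
          cols[[paste0(cv, ".", lv)]] <- as.numeric(x == lv)
        }
      }
    } else {
      cols[[cv]] <- as.numeric(x)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  info <- tibble(column = colnames(x), role = "covariate", base = NA_character_)
  if (interactions) {
    if (anyNA(x)) {
      abort("design has missing covariate values; impute before requesting treatment interactions")
    }
    z <- as.numeric(cohort$treatment)
    zx <- x * z
    colnames(zx) <- paste0("Z:", colnames(x))
    x <- cbind(x, Z = z, zx)
    info <- dplyr::bind_rows(
      info,
      tibble(column = "Z", role = "treatment", base = NA_character_),
      tibble(column = colnames(zx), role = "interaction", base = info$column)
    )
  }
  list(x = x, info = info)
}

#' Rewrite the treatment arm of an encoded design
#'
#' Sets the treatment column `Z` to `z` and recomputes every `Z:x`
#' interaction column from its base covariate column, leaving all covariate
#' columns untouched. This is the counterfactual "twin" construction.
#'
#' @param design a design list from [encode_design()] with
#'   `interactions = TRUE`.
#' @param z new treatment values, length 1 or `nrow(x)`.
#' @return the design list with `x` rewritten.
#' @export
set_treatment <- function(design, z) {
  info <- design$info
  if (!"Z" %in% info$column) abort("design was encoded without treatment interactions")
  x <- design$x
  z <- rep_len(as.numeric(z), nrow(x))
  x[, "Z"] <- z
  inter <- dplyr::filter(info, .data$role == "interaction")
  for (i in seq_len(nrow(inter))) {
    x[, inter$column[[i]]] <- x[, inter$base[[i]]] * z
  }
  design$x <- x
  design
}
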