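Package: survtwin
Title: Virtual-Twin Survival Forests for Individualized Treatment Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized estimation of the survival benefit or harm of an
    adjuvant treatment from observational cohorts, built around random
    survival forests with treatment-interaction terms and virtual-twin
    counterfactual prediction. Provides overlap ("virtual equipoise")
    trimming via an out-of-bag treatment-probability forest, iterative
    forest imputation of missing staging covariates, a random survival
    forest engine with log-rank splitting and Nelson-Aalen terminal nodes,
    restricted-mean-survival-time gain/loss accounting stratified by
    pathologic tumor (pT) and nodal (pN) categories, and a synthetic
    esophageal-cancer cohort generator with closed-form ground-truth
    individual treatment effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    ranger,
    survival,
    stats,
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
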