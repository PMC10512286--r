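Package: agingpanel
Title: Tissue-Specific Survival Biomarker Panels from Candidate Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of small additive gene-expression panels
    for time-to-event endpoints. Screens a candidate gene list by covariate-
    adjusted univariable Cox proportional-hazards models, assembles survivors
    into one additive multivariable panel guarded by variance-inflation-factor
    diagnostics, re-evaluates the panel within clinically defined strata
    (histologic grade, age, cytogenetic risk), combines per-cohort stratified
    Wald p-values by the harmonic mean with Benjamini-Hochberg correction
    across subgroups, and calibrates the panel against a random-gene-set
    permutation null. Ships a proportional-hazards cohort simulator so the
    whole pipeline is testable without access-controlled clinical data. The
    Cox engine (Efron/Breslow partial likelihood, Newton-Raphson, observed-
    information Wald inference) is implemented in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
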