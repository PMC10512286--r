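#' Fit the additive multivariable panel model
#'
#' One Cox model containing all panel genes additively, optionally plus
#' adjustment covariates; the global Wald test over the gene terms is the
#' panel's joint significance.
#'
#' @param cohort An `aging_cohort`.
#' @param panel An `aging_panel` or a character vector of gene columns.
#' @param adjust_covariates Covariate columns to adjust for, or `NULL`
#'   for the crude panel model.
#' @param ties Tie handling passed to [fit_cox()].
#' @return A `cox_fit` with the global Wald test over the gene terms.
#' @export
fit_panel <- function(cohort, panel, adjust_covariates = NULL, ties = "efron") {
  genes <- panel_genes(panel)
  if (length(genes) == 0L) abort("panel is empty")
  missing <- setdiff(genes, cohort_genes(cohort))
  if (length(missing) > 0L)
    abort(sprintf("panel gene(s) missing from cohort '%s': %s",
                  cohort_name(cohort), paste(missing, collapse = ", ")))
  fit_cox(cox_design(cohort, genes, adjust_covariates %||% character()), ties = ties)
}

panel_genes <- function(panel) {
  if (inherits(panel, "aging_panel")) panel$genes else as.character(panel)
}

#' Per-patient panel risk score
#'
#' The linear predictor of the fitted panel's gene terms,
#' sum(beta_g * x_g), evaluated on any cohort carrying the panel genes.
#' No dichotomization threshold is applied.
#'
#' @param cohort An `aging_cohort`.
#' @param fit A `cox_fit` whose gene terms are present in the cohort.
#' @return Tibble with `sample_id` and `risk_score`.
#' @export
risk_scores <- function(cohort, fit) {
  genes <- fit$term_names[fit$roles == "gene"]
  missing <- setdiff(genes, cohort_genes(cohort))
  if (length(missing) > 0L)
    abort(sprintf("gene(s) missing from cohort: %s", paste(missing, collapse = ", ")))
  x <- as.matrix(cohort[, genes, drop = FALSE])
  tibble::tibble(sample_id = cohort$sample_id,
                 risk_score = drop(x %*% fit$beta[genes]))
}

#' Define a stratification rule
#'
#' Rules partition every sample into exactly one stratum:
#' * `grade` — Gleason pairs 3+3 / 3+4 ("low_grade", the clinically
#'   favorable group) vs every other pair ("high_grade");
#' * `age` — `age <= cutoff` ("younger") vs `age > cutoff` ("older");
#'   conventional cutoffs are 60 (prostate) and 56 (AML);
#' * `risk` — favorable vs unfavorable cytogenetic risk.
#'
#' @param axis One of `"grade"`, `"age"`, `"risk"`.
#' @param cutoff Age cutoff in years (required for `axis = "age"`).
#' @param low_pairs Gleason pairs defining the low-grade group.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(axis = c("grade", "age", "risk"), cutoff = NULL,
                         low_pairs = c("3+3", "3+4")) {
  axis <- match.arg(axis)
  if (axis == "age" && is.null(cutoff)) abort("age stratification needs a cutoff")
  structure(list(axis = axis, cutoff = cutoff, low_pairs = low_pairs),
            class = "stratum_spec")
}

stratum_labels <- function(cohort, spec) {
  switch(spec$axis,
    grade = {
      if (!all(c("gleason_major", "gleason_minor") %in% names(cohort)))
        abort("cohort has no Gleason columns; grade stratification unavailable")
      pair <- paste0(cohort$gleason_major, "+", cohort$gleason_minor)
      ifelse(pair %in% spec$low_pairs, "low_grade", "high_grade")
    },
    age = ifelse(cohort$age <= spec$cutoff, "younger", "older"),
    risk = {
      if (!"risk_category" %in% names(cohort))
        abort("cohort has no risk_category column; risk stratification unavailable")
      cohort$risk_category
    }
  )
}

spec_levels <- function(spec) {
  switch(spec$axis,
    grade = c("low_grade", "high_grade"),
    age = c("younger", "older"),
    risk = c("favorable", "unfavorable")
  )
}

#' Split a cohort into strata
#'
#' Applies a stratification rule and returns one sub-cohort per stratum
#' label (possibly with zero rows); the partition is disjoint and
#' exhaustive, so the union of the strata reconstructs the cohort.
#'
#' @param cohort An `aging_cohort`.
#' @param spec A `stratum_spec`.
#' @return Named list of `aging_cohort` tibbles.
#' @export
stratify <- function(cohort, spec) {
  lab <- stratum_labels(cohort, spec)
  out <- lapply(spec_levels(spec), function(lv) {
    sub <- cohort[lab == lv, , drop = FALSE]
    as_cohort_like(sub, cohort, name = paste0(cohort_name(cohort), ":", lv))
  })
  names(out) <- spec_levels(spec)
  inform(sprintf("stratify[%s]: %s", spec$axis,
                 paste(sprintf("%s n=%d", names(out), vapply(out, nrow, 0L)),
                       collapse = ", ")))
  out
}

#' Evaluate the panel within strata
#'
#' Refits the additive panel model separately in each stratum of each
#' rule. Within-stratum fits are unadjusted by default (the stratifying
#' variable is controlled by design; `adjust_covariates` re-enables
#' adjustment by other covariates for sensitivity analysis — the
#' stratifying axis itself is always excluded). Strata with no samples or
#' no events are marked not analyzable rather than failing the run.
#'
#' @param cohort An `aging_cohort`.
#' @param panel An `aging_panel` or character vector of genes.
#' @param specs A `stratum_spec` or list of them.
#' @param adjust_covariates Optional covariates for within-stratum
#'   adjustment (default none).
#' @param ties Tie handling passed to [fit_cox()].
#' @return A tibble, one row per (axis, stratum): `axis`, `label`, `n`,
#'   `n_events`, `analyzable`, `global_wald_p`, `converged`, and the
#'   `cox_fit` in the `fit` list-column.
#' @export
evaluate_strata <- function(cohort, panel, specs, adjust_covariates = NULL,
                            ties = "efron") {
  if (inherits(specs, "stratum_spec")) specs <- list(specs)
  purrr::map_dfr(specs, function(spec) {
    covs <- setdiff(adjust_covariates %||% character(),
                    switch(spec$axis, grade = "grade", risk = "grade", age = "age"))
    strata <- withCallingHandlers(stratify(cohort, spec),
                                  message = function(m) invokeRestart("muffleMessage"))
    purrr::map_dfr(names(strata), function(lv) {
      sub <- strata[[lv]]
      base <- tibble::tibble(axis = spec$axis, label = lv, n = nrow(sub),
                             n_events = if (nrow(sub)) sum(sub$event) else 0L)
      if (base$n == 0L || base$n_events == 0L) {
        return(dplyr::mutate(base, analyzable = FALSE, global_wald_p = NA_real_,
                             converged = NA, fit = list(NULL)))
      }
      fit <- tryCatch(fit_panel(sub, panel, adjust_covariates = covs, ties = ties),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        return(dplyr::mutate(base, analyzable = FALSE, global_wald_p = NA_real_,
                             converged = NA, fit = list(conditionMessage(fit))))
      }
      dplyr::mutate(base, analyzable = TRUE, global_wald_p = fit$global$p,
                    converged = fit$converged, fit = list(fit))
    })
  })
}
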