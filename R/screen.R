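#' Screen candidate genes by adjusted univariable Cox models
#'
#' For each candidate gene present in the cohort, fits two univariable
#' Cox models: the crude model (gene alone) and the adjusted model (gene
#' plus the adjustment covariates, typically Gleason-sum grade and age).
#' Both hazard ratios and Wald p-values are kept so a two-stage funnel
#' (crude significance, then adjusted significance) can be read from one
#' pass. Candidates absent from the expression data are reported in the
#' `missing_genes` attribute, never silently dropped.
#'
#' No multiple-testing correction is applied at this stage by default
#' (robustness is deferred to external validation and the random-panel
#' null); `p_adjust = TRUE` adds BH-adjusted columns for users who want
#' them.
#'
#' @param cohort An `aging_cohort`.
#' @param candidates Character vector of candidate gene symbols.
#' @param adjust_covariates Adjustment covariate columns (default
#'   `c("grade", "age")`); use `character()` for a crude-only screen.
#' @param alpha Significance level recorded with the records (used
#'   downstream by [select_panel()]).
#' @param p_adjust Add BH-corrected `crude_p_bh` / `adj_p_bh` columns.
#' @param ties Tie handling passed to [fit_cox()].
#' @return A `screen_records` tibble, one row per present candidate:
#'   `gene`, `crude_hr`, `crude_p`, `adj_hr`, `adj_p`, `n_used`,
#'   `converged`. Attributes: `missing_genes`, `alpha`,
#'   `adjust_covariates`, `cohort_name`.
#' @export
screen_genes <- function(cohort, candidates, adjust_covariates = c("grade", "age"),
                         alpha = 0.05, p_adjust = FALSE, ties = "efron") {
  if (length(candidates) == 0L) abort("no candidate genes supplied")
  present <- intersect(candidates, cohort_genes(cohort))
  missing <- setdiff(candidates, present)
  if (length(present) == 0L) abort("none of the candidate genes are present in the cohort")
  if (length(missing) > 0L)
    inform(sprintf("screen_genes: %d candidate(s) absent from the expression matrix: %s",
                   length(missing), paste(missing, collapse = ", ")))

  rows <- purrr::map(present, function(g) {
    crude <- fit_cox(cox_design(cohort, g), ties = ties)
    if (length(adjust_covariates) > 0L) {
      adj <- fit_cox(cox_design(cohort, g, adjust_covariates), ties = ties)
    } else {
      adj <- crude
    }
    tibble::tibble(
      gene = g,
      crude_hr = unname(crude$hr[g]), crude_p = unname(crude$wald_p[g]),
      adj_hr = unname(adj$hr[g]), adj_p = unname(adj$wald_p[g]),
      n_used = adj$n, converged = crude$converged && adj$converged
    )
  })
  records <- dplyr::bind_rows(rows)
  if (p_adjust) {
    records$crude_p_bh <- bh_fdr(records$crude_p)
    records$adj_p_bh <- bh_fdr(records$adj_p)
  }
  structure(records, missing_genes = missing, alpha = alpha,
            adjust_covariates = adjust_covariates,
            cohort_name = cohort_name(cohort),
            class = c("screen_records", class(records)))
}

#' Select a panel from screening records
#'
#' Keeps the genes whose (adjusted, by default) Wald p falls below
#' `alpha`, ordered by ascending p, then checks multicollinearity among
#' the selected genes' expression with [vif()]: any VIF at or above the
#' threshold rejects the panel with an error naming the offending gene.
#' An empty selection yields an empty panel with a warning so a pipeline
#' can halt downstream stages gracefully.
#'
#' @param records A `screen_records` tibble from [screen_genes()].
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Select on `adj_p` (default) or `crude_p`.
#' @param vif_threshold Multicollinearity cutoff (default 5).
#' @param cohort The cohort the records came from (needed for the joint
#'   VIF computation).
#' @return An `aging_panel`: ordered genes, thresholds used, VIF table,
#'   and source cohort name.
#' @export
select_panel <- function(records, alpha = 0.05, use_adjusted = TRUE,
                         vif_threshold = 5, cohort = NULL) {
  if (nrow(records) == 0L) abort("no screening records supplied")
  p <- if (use_adjusted) records$adj_p else records$crude_p
  keep <- records[!is.na(p) & p < alpha, , drop = FALSE]
  keep <- keep[order(if (use_adjusted) keep$adj_p else keep$crude_p), , drop = FALSE]
  genes <- keep$gene
  vif_tab <- NULL
  if (length(genes) == 0L) {
    warn(sprintf("no gene passed the screen at alpha = %g; panel is empty", alpha))
  } else if (length(genes) >= 2L) {
    if (is.null(cohort)) abort("cohort is required to compute panel VIFs")
    vif_tab <- vif(as.matrix(cohort[, genes, drop = FALSE]), threshold = vif_threshold)
    bad <- vif_tab$term[!vif_tab$below_threshold]
    if (length(bad) > 0L)
      abort(sprintf("panel rejected: VIF >= %g for gene(s): %s",
                    vif_threshold, paste(bad, collapse = ", ")))
  }
  structure(list(
    genes = genes, alpha = alpha, use_adjusted = use_adjusted,
    adjust_covariates = attr(records, "adjust_covariates"),
    vif_threshold = vif_threshold, vif = vif_tab,
    cohort_name = attr(records, "cohort_name") %||%
      (if (!is.null(cohort)) cohort_name(cohort) else NA_character_)
  ), class = "aging_panel")
}

#' @export
print.aging_panel <- function(x, ...) {
  cat(sprintf("Gene panel from cohort '%s' (%s p < %g):\n", x$cohort_name,
              if (x$use_adjusted) "adjusted" else "crude", x$alpha))
  if (length(x$genes) == 0L) cat("  <empty>\n") else
    cat(sprintf("  %s\n", paste(x$genes, collapse = ", ")))
  if (!is.null(x$vif))
    cat(sprintf("  max VIF %.3g (threshold %g)\n", max(x$vif$vif), x$vif_threshold))
  invisible(x)
}

#' @export
tidy.aging_panel <- function(x, ...) {
  tibble::tibble(
    gene = x$genes, rank = seq_along(x$genes),
    vif = if (is.null(x$vif)) NA_real_ else x$vif$vif[match(x$genes, x$vif$term)]
  )
}
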