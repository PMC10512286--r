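#' Harmonic-mean combination of p-values
#'
#' Combines one subgroup's per-cohort p-values as the plain harmonic mean
#' `n / sum(1/p)` (for two values `2xy/(x+y)`, for three
#' `3xyz/(xy+yz+xz)`). The result is bounded by the smallest and largest
#' input and is strictly increasing in every argument. The `"printed"`
#' variant keeps the constant at 2 for any n (`2 / sum(1/p)`), a form
#' that circulates in the applied literature with a typographic origin;
#' it is provided for audit only and is not the default.
#'
#' @param ps Numeric vector of p-values in (0, 1].
#' @param variant `"standard"` (default) or `"printed"`.
#' @return A single combined p-value.
#' @export
harmonic_mean_p <- function(ps, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  if (length(ps) < 1L) abort("need at least one p-value")
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1))
    abort("p-values must lie in (0, 1]")
  if (length(ps) == 1L) return(ps)
  k <- if (variant == "standard") length(ps) else 2
  k / sum(1 / ps)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort, multiply p_(i) by m/i, enforce
#' monotonicity from the largest rank down, cap at 1; values return in
#' input order. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param ps Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(ps) {
  if (length(ps) == 0L) abort("need at least one p-value")
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(ps, method = "BH")
}

#' Integrate per-cohort subgroup p-values across cohorts
#'
#' For each subgroup (e.g. the four strata low grade / high grade /
#' younger / older), combines its per-cohort panel Wald p-values with the
#' harmonic mean, then applies BH correction across the subgroup family.
#' When only part of the family is supplied, `family_size` fixes the BH
#' family size m (absent subgroups are treated as ranking above every
#' observed one, the configuration under which BH ranks are unaffected).
#'
#' @param data Tibble or data frame with columns `subgroup` and `p`
#'   (optionally `cohort`), one row per (subgroup, cohort) p-value; or a
#'   named list of numeric vectors.
#' @param variant Harmonic-mean variant, see [harmonic_mean_p()].
#' @param family_size BH family size m; defaults to the number of
#'   subgroups present.
#' @return Tibble, one row per subgroup in first-appearance order:
#'   `subgroup`, `n_cohorts`, `cohort_ps` (list-column),
#'   `raw_integrated_p`, `fdr_adjusted_p`, `m`.
#' @export
integrate_subgroups <- function(data, variant = "standard", family_size = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble::tibble(
      subgroup = rep(names(data), lengths(data)),
      p = unlist(data, use.names = FALSE)
    )
  }
  if (!all(c("subgroup", "p") %in% names(data)))
    abort("data needs 'subgroup' and 'p' columns")
  if (nrow(data) == 0L) abort("no p-values to integrate")
  if ("cohort" %in% names(data)) {
    sets <- tapply(data$cohort, data$subgroup, function(x) paste(sort(x), collapse = "|"))
    if (length(unique(sets)) > 1L)
      warn("cohort sets differ across subgroups; integrating what exists")
  }
  groups <- unique(data$subgroup)
  ps <- lapply(groups, function(g) data$p[data$subgroup == g])
  raw <- vapply(ps, harmonic_mean_p, numeric(1L), variant = variant)
  m <- family_size %||% length(groups)
  if (m < length(groups)) abort("family_size smaller than the number of subgroups")
  adj <- bh_fdr_family(raw, m)
  tibble::tibble(
    subgroup = groups, n_cohorts = lengths(ps), cohort_ps = ps,
    raw_integrated_p = raw, fdr_adjusted_p = adj, m = m
  )
}

# BH step-up with family size m >= length(ps): the absent family members
# are assumed to rank above (exceed) every observed value, so observed
# ranks are 1..k in sorted order.
bh_fdr_family <- function(ps, m) {
  k <- length(ps)
  o <- order(ps)
  adj <- ps[o] * m / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
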