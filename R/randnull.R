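#' Random-gene-set permutation null for a panel
#'
#' Draws `R` panels of `k` distinct genes uniformly from all genes in the
#' cohort's expression matrix (the discovered panel's own genes are not
#' excluded), fits each as one additive Cox model — crude by default,
#' matching how the comparison is usually run — and records its global
#' Wald p-value. The nominal p is the fraction of repetitions whose p
#' reached or outperformed the observed panel's (`count / R`);
#' repetitions that fail to converge are excluded from the sample and
#' counted. With `adjust = TRUE` the random fits include the adjustment
#' covariates, and the supplied `observed_p` must then also come from an
#' adjusted fit for a like-with-like comparison.
#'
#' @param cohort An `aging_cohort`.
#' @param k Panel size to match.
#' @param R Number of repetitions.
#' @param observed_p The observed panel's global Wald p-value, in (0, 1].
#' @param seed Integer seed (reproducible null given the same seed).
#' @param adjust Include adjustment covariates in the random fits.
#' @param adjust_covariates Covariates used when `adjust = TRUE`.
#' @param estimator `"count"` for `count / R` (can be zero) or
#'   `"add_one"` for `(count + 1) / (R + 1)`.
#' @param ties Tie handling passed to the Cox engine.
#' @return A `null_distribution`: the random p sample, the observed p,
#'   and the nominal empirical p.
#' @export
random_panel_null <- function(cohort, k, R, observed_p, seed = NULL,
                              adjust = FALSE, adjust_covariates = c("grade", "age"),
                              estimator = c("count", "add_one"), ties = "efron") {
  estimator <- match.arg(estimator)
  genes <- cohort_genes(cohort)
  if (length(genes) < k + 1L) abort("gene universe must exceed the panel size")
  if (R < 1L) abort("R must be at least 1")
  if (!is.finite(observed_p) || observed_p <= 0 || observed_p > 1)
    abort("observed_p must lie in (0, 1]")
  covs <- if (adjust) adjust_covariates else character()

  # presort once; every random fit reuses the ordered rows
  ord <- order(cohort$time)
  xall <- as.matrix(cohort[ord, c(genes, covs), drop = FALSE])
  time <- cohort$time[ord]
  event <- as.integer(cohort$event[ord])
  ncov <- length(covs)
  roles <- c(rep("gene", k), rep("adjust", ncov))

  draw <- function() {
    ps <- numeric(R)
    failed <- 0L
    for (r in seq_len(R)) {
      idx <- sample.int(length(genes), k)
      x <- xall[, c(idx, length(genes) + seq_len(ncov)), drop = FALSE]
      fit <- fit_cox_raw(x, time, event, roles = roles, ties = ties, presorted = TRUE)
      if (fit$converged && is.finite(fit$global$p)) {
        ps[r] <- fit$global$p
      } else {
        ps[r] <- NA_real_
        failed <- failed + 1L
      }
    }
    list(ps = ps[!is.na(ps)], failed = failed)
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  count <- sum(res$ps <= observed_p)
  nominal <- switch(estimator, count = count / R, add_one = (count + 1) / (R + 1))
  structure(list(
    k = k, R = R, random_ps = res$ps, observed_p = observed_p,
    nominal_p = nominal, estimator = estimator, n_failed = res$failed,
    seed = seed, universe_size = length(genes), adjusted = adjust
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "Random %d-gene panel null: R = %d (%d failed), universe = %d genes\n",
    x$k, x$R, x$n_failed, x$universe_size))
  cat(sprintf("observed p = %.3g, nominal empirical p = %.4g (%s estimator)\n",
              x$observed_p, x$nominal_p, x$estimator))
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$random_ps), random_p = x$random_ps)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    k = x$k, R = x$R, n_failed = x$n_failed, universe_size = x$universe_size,
    observed_p = x$observed_p, nominal_p = x$nominal_p,
    estimator = x$estimator, adjusted = x$adjusted
  )
}

#' Histogram of the random-panel null
#'
#' @param object A `null_distribution`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot of the random Wald p-values with the observed panel's
#'   p marked as a vertical line.
#' @export
autoplot.null_distribution <- function(object, bins = 50, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$random_p)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_p, colour = "black",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("Global Wald p of random %d-gene panels", object$k),
      y = "Count",
      title = sprintf("Random-panel null (R = %d, nominal p = %.3g)",
                      object$R, object$nominal_p)
    )
}
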