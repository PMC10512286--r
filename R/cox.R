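#' Build a Cox design from a cohort
#'
#' Assembles the term matrix, follow-up time and event flag for
#' [fit_cox()]. Gene terms carry role `"gene"` and adjustment covariates
#' role `"adjust"`; the global Wald test is taken over the gene terms.
#'
#' @param cohort An `aging_cohort` tibble.
#' @param genes Character vector of gene columns to include.
#' @param covariates Character vector of adjustment covariate columns
#'   (typically `c("grade", "age")`), or `character()` for a crude model.
#' @return A `cox_design` list with elements `x`, `time`, `event`, `roles`.
#' @export
cox_design <- function(cohort, genes, covariates = character()) {
  terms <- c(genes, covariates)
  missing <- setdiff(terms, names(cohort))
  if (length(missing) > 0L)
    abort(sprintf("term(s) not present in cohort: %s", paste(missing, collapse = ", ")))
  x <- as.matrix(cohort[, terms, drop = FALSE])
  storage.mode(x) <- "double"
  new_cox_design(x, cohort$time, cohort$event,
                 roles = c(rep("gene", length(genes)), rep("adjust", length(covariates))))
}

new_cox_design <- function(x, time, event, roles) {
  if (length(roles) != ncol(x)) abort("roles must match design columns")
  if (nrow(x) != length(time) || nrow(x) != length(event))
    abort("design rows must align with time and event")
  structure(list(x = x, time = as.numeric(time), event = as.integer(event),
                 roles = roles),
            class = "cox_design")
}

check_design <- function(design) {
  x <- design$x
  if (sum(design$event) < 1L) abort("design has no events")
  csd <- apply(x, 2L, stats::sd)
  if (any(csd == 0))
    abort(sprintf("constant design column(s): %s",
                  paste(colnames(x)[csd == 0], collapse = ", ")))
  if (ncol(x) > 1L && anyDuplicated(t(x)) > 0L)
    abort("duplicated design column(s)")
  invisible(design)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood by Newton-Raphson from beta = 0 with
#' step halving, using the Efron tie approximation by default (Breslow
#' selectable). Standard errors come from the observed information at the
#' maximum; per-term Wald z tests and a global Wald chi-square over the
#' gene terms are reported. Non-convergence and separation (a coefficient
#' escaping beyond +/-50) yield a flagged fit, not an error.
#'
#' @param design A `cox_design` from [cox_design()].
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @param tol Convergence tolerance on the largest Newton step
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return A `cox_fit` object; see [tidy.cox_fit()] and
#'   [glance.cox_fit()].
#' @export
fit_cox <- function(design, ties = c("efron", "breslow"), tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  check_design(design)
  fit_cox_raw(design$x, design$time, design$event, roles = design$roles,
              ties = ties, tol = tol, max_iter = max_iter)
}

# Newton-Raphson driver over the compiled likelihood kernel. Assumes the
# caller has validated the design; `presorted` skips the time sort when the
# rows already come ordered (the random-null hot path).
fit_cox_raw <- function(x, time, event, roles = rep("gene", ncol(x)),
                        ties = "efron", tol = 1e-8, max_iter = 50L,
                        presorted = FALSE) {
  method <- if (ties == "efron") 1L else 0L
  if (!presorted) {
    ord <- order(time)
    x <- x[ord, , drop = FALSE]
    time <- time[ord]
    event <- event[ord]
  }
  p <- ncol(x)
  beta <- rep(0, p)
  ev0 <- cox_eval(x, time, event, beta, method)
  loglik_null <- ev0$loglik
  ev <- ev0
  converged <- FALSE
  flag <- NA_character_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) NULL)
    if (is.null(step)) {
      flag <- "singular information"
      break
    }
    # step halving keeps the partial likelihood non-decreasing
    h <- 1
    repeat {
      cand <- beta + h * step
      ev_new <- cox_eval(x, time, event, cand, method)
      if (ev_new$loglik >= ev$loglik - 1e-12 || h < 1 / 1024) break
      h <- h / 2
    }
    beta <- cand
    ev <- ev_new
    if (any(abs(beta) > 50)) {
      flag <- "separation"
      break
    }
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.na(flag)) flag <- "max iterations reached"

  vcov <- tryCatch(solve(ev$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  pvals <- 2 * pnorm(-abs(z))
  term_names <- colnames(x) %||% paste0("x", seq_len(p))

  fit <- structure(list(
    term_names = term_names, roles = roles,
    beta = setNames(beta, term_names), se = setNames(se, term_names),
    hr = setNames(exp(beta), term_names),
    ci95 = cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se)),
    wald_z = setNames(z, term_names), wald_p = setNames(pvals, term_names),
    vcov = `dimnames<-`(vcov, list(term_names, term_names)),
    info = `dimnames<-`(ev$info, list(term_names, term_names)),
    loglik = ev$loglik, loglik_null = loglik_null,
    n = nrow(x), n_events = sum(event),
    iterations = iter, converged = converged, flag = flag, ties = ties
  ), class = "cox_fit")
  gene_terms <- term_names[roles == "gene"]
  fit$global <- if (length(gene_terms) > 0L && converged) {
    wald_global(fit, gene_terms)
  } else {
    list(stat = NA_real_, df = length(gene_terms), p = NA_real_, terms = gene_terms)
  }
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, %s after %d iterations\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "converged" else paste0("NOT converged (", x$flag, ")"),
              x$iterations))
  print(tidy(x), ...)
  if (!is.na(x$global$p))
    cat(sprintf("Global Wald over %d gene term(s): chi-square = %.4g, p = %.4g\n",
                x$global$df, x$global$stat, x$global$p))
  invisible(x)
}

#' Global Wald test over a subset of fitted terms
#'
#' Quadratic form of the selected coefficients against the inverse of the
#' corresponding covariance block, referred to a chi-square with one
#' degree of freedom per term. For a single term this reduces exactly to
#' the square of its Wald z.
#'
#' @param fit A `cox_fit`.
#' @param terms Nonempty character vector of fitted term names.
#' @return List with `stat`, `df`, `p`, `terms`.
#' @export
wald_global <- function(fit, terms) {
  if (length(terms) == 0L) abort("wald_global needs a nonempty term set")
  missing <- setdiff(terms, fit$term_names)
  if (length(missing) > 0L)
    abort(sprintf("term(s) not in fit: %s", paste(missing, collapse = ", ")))
  b <- fit$beta[terms]
  v <- fit$vcov[terms, terms, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(v, b)), error = function(e) NA_real_)
  df <- length(terms)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE), terms = terms)
}

#' Score test at beta = 0
#'
#' U(0)' I(0)^-1 U(0) for a design; with a single binary covariate and no
#' tied event times this equals the log-rank statistic.
#'
#' @param design A `cox_design`.
#' @param ties Tie handling, as in [fit_cox()].
#' @return List with `stat`, `df`, `p`.
#' @export
cox_score_test <- function(design, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ord <- order(design$time)
  ev <- cox_eval(design$x[ord, , drop = FALSE], design$time[ord],
                 design$event[ord], rep(0, ncol(design$x)),
                 if (ties == "efron") 1L else 0L)
  stat <- drop(t(ev$grad) %*% solve(ev$info, ev$grad))
  df <- ncol(design$x)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# partial log-likelihood at an arbitrary beta (test oracle hook)
cox_loglik <- function(design, beta, ties = "efron") {
  ord <- order(design$time)
  cox_eval(design$x[ord, , drop = FALSE], design$time[ord], design$event[ord],
           beta, if (ties == "efron") 1L else 0L)$loglik
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from the least-squares
#' regression of column j on all other columns (with intercept). Exactly
#' collinear columns are reported as `Inf` and flagged.
#'
#' @param x Numeric matrix (>= 3 rows, >= 2 columns), e.g. the selected
#'   panel genes' expression.
#' @param threshold Multicollinearity threshold; the conventional cutoff
#'   is 5.
#' @return Tibble with columns `term`, `vif`, `below_threshold`.
#' @export
vif <- function(x, threshold = 5) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) abort("vif needs at least 3 samples")
  if (ncol(x) < 2L) abort("vif needs at least 2 columns")
  terms <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  v <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  tibble::tibble(term = terms, vif = v, below_threshold = is.finite(v) & v < threshold)
}

#' Tidy a Cox fit
#'
#' One row per model term: log-hazard coefficient, standard error, hazard
#' ratio with 95% Wald interval on the log scale, Wald z and p.
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = x$term_names, role = x$roles,
    estimate = unname(x$beta), std.error = unname(x$se),
    hr = unname(x$hr),
    conf.low = unname(x$ci95[, "lower"]), conf.high = unname(x$ci95[, "upper"]),
    statistic = unname(x$wald_z), p.value = unname(x$wald_p)
  )
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One-row tibble with sample and event counts, log partial
#'   likelihoods, the global gene-term Wald test, and convergence state.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    loglik = x$loglik, loglik_null = x$loglik_null,
    global_wald_stat = x$global$stat, global_df = x$global$df,
    global_wald_p = x$global$p,
    iterations = x$iterations, converged = x$converged, ties = x$ties
  )
}

#' Forest plot of hazard ratios
#'
#' @param object A `cox_fit`.
#' @param ... Unused.
#' @return A ggplot: per-term hazard ratios with 95% confidence intervals
#'   on a log scale.
#' @export
autoplot.cox_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$term, colour = .data$role)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL)
}
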