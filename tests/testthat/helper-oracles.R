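# Shared fixtures and independent oracles for the test suite.

# Small survival fixture: distinct follow-up times, one binary covariate.
tiny_surv_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    list(
      x = matrix(sample(c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))),
                 ncol = 1, dimnames = list(NULL, "x")),
      time = sort(sample(seq_len(50 * n), n)) / 10, # distinct by construction
      event = pmax(rbinom(n, 1, 0.7), c(1, rep(0, n - 1))) # at least one event
    )
  })
}

tiny_design <- function(fx) {
  agingpanel:::new_cox_design(fx$x, fx$time, fx$event, roles = "gene")
}

# Golden-section maximization of the 1-D partial likelihood: the brute-force
# oracle for the Newton-Raphson estimate.
golden_max_beta <- function(design, lower = -20, upper = 20, tol = 1e-10) {
  f <- function(b) agingpanel:::cox_loglik(design, b)
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
  opt$maximum
}

# Brute-force Benjamini-Hochberg by its definition:
# adj_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, in input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(m * ps[i:m] / (i:m)), numeric(1))
  pmin(adj, 1)[order(o)]
}

# Cohort with planted log-hazard effects on the named candidate genes.
planted_cohort <- function(n = 300, betas = NULL, seed = 1, censoring = 0.4,
                           n_genes = 500) {
  if (is.null(betas))
    betas <- c(CD44 = log(0.5), GADD45B = log(0.5), STAT3 = log(0.5),
               GFAP = log(0.5))
  cfg <- sim_config(
    n_samples = n, n_genes = n_genes, signal_genes = betas,
    baseline_rate = 0.002, gamma_grade = 0.25, gamma_age = 0.2,
    grade_type = "gleason", age_mean = 60, age_sd = 8,
    censoring_target = censoring, rho = 0.1, seed = seed
  )
  simulate_cohort(cfg)$cohort
}

null_cohort <- function(seed = 1, n = NULL) {
  cfg <- sim_preset("null", seed = seed)
  if (!is.null(n)) cfg$n_samples <- as.integer(n)
  simulate_cohort(cfg)$cohort
}

# Expand a per-Gleason-score count table into a minimal analyzable cohort
# (dummy expression/survival; only the grade columns matter downstream).
cohort_from_gleason_counts <- function(scores, counts, name = "counts") {
  n <- sum(counts)
  parts <- strsplit(rep(scores, counts), "+", fixed = TRUE)
  ids <- sprintf("P%04d", seq_len(n))
  clinical <- tibble::tibble(
    sample_id = ids, time = seq_len(n), event = rep(1L, n), age = 60,
    gleason_major = as.integer(vapply(parts, `[`, "", 1)),
    gleason_minor = as.integer(vapply(parts, `[`, "", 2))
  )
  expr <- matrix(seq_len(n), nrow = 1, dimnames = list("DUMMY", ids))
  assemble_cohort(expr, clinical, name = name)
}

expect_silent_messages <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}
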