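test_that("sign and scale reparameterizations behave as they must", {
  fx <- tiny_surv_fixture(30, seed = 11)
  d_pos <- tiny_design(fx)
  f_pos <- fit_cox(d_pos)

  fx_neg <- fx
  fx_neg$x <- -fx$x
  f_neg <- fit_cox(tiny_design(fx_neg))
  expect_equal(unname(f_neg$beta), -unname(f_pos$beta), tolerance = 1e-10)
  expect_equal(unname(f_neg$wald_p), unname(f_pos$wald_p), tolerance = 1e-12)
  expect_equal(f_neg$loglik, f_pos$loglik, tolerance = 1e-12)

  fx_sc <- fx
  fx_sc$x <- fx$x * 4
  f_sc <- fit_cox(tiny_design(fx_sc))
  expect_equal(unname(f_sc$beta), unname(f_pos$beta) / 4, tolerance = 1e-8)
  expect_equal(unname(f_sc$wald_p), unname(f_pos$wald_p), tolerance = 1e-10)
})

test_that("Newton-Raphson matches golden-section maximization on small fixtures", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 5)
    fx <- tiny_surv_fixture(n, seed = seed)
    if (sd(fx$x) == 0) next
    d <- tiny_design(fx)
    f <- fit_cox(d)
    expect_gte(f$loglik, agingpanel:::cox_loglik(d, 0))
    gm <- golden_max_beta(d)
    if (!f$converged || abs(gm) >= 10) next # no interior maximum to compare
    expect_lt(abs(unname(f$beta) - gm), 1e-4)
  }
})

test_that("estimates and p-values agree with an independent implementation", {
  skip_if_not_installed("survival")
  sim <- simulate_cohort(sim_preset("pc_like", seed = 21))
  co <- sim$cohort
  for (ties in c("efron", "breslow")) {
    f <- fit_cox(cox_design(co, c("CD44", "GFAP"), c("grade", "age")), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ CD44 + GFAP + grade + age,
                           data = co, ties = ties)
    expect_equal(unname(f$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("tie handling: Efron and Breslow agree exactly without ties, differ with", {
  fx <- tiny_surv_fixture(25, seed = 42)
  d <- tiny_design(fx)
  fe <- fit_cox(d, ties = "efron")
  fb <- fit_cox(d, ties = "breslow")
  expect_equal(unname(fe$beta), unname(fb$beta), tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)

  cfg <- sim_config(n_samples = 120, n_genes = 5, round_times = TRUE, seed = 8,
                    signal_genes = c(CD44 = log(0.5)))
  co <- simulate_cohort(cfg)$cohort
  de <- cox_design(co, "CD44")
  f1 <- fit_cox(de, ties = "efron")
  f2 <- fit_cox(de, ties = "breslow")
  expect_false(isTRUE(all.equal(f1$beta, f2$beta, tolerance = 1e-8)))
  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(time, event) ~ CD44, data = co, ties = "efron")
  expect_equal(unname(f1$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("score test at beta = 0 equals the log-rank statistic", {
  skip_if_not_installed("survival")
  for (seed in c(2, 7, 19)) {
    fx <- tiny_surv_fixture(18, seed = seed)
    if (sd(fx$x) == 0) next
    d <- tiny_design(fx)
    st <- cox_score_test(d)
    lr <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ fx$x)
    expect_lt(abs(st$stat - lr$chisq), 1e-8)
  }
})

test_that("degenerate designs error or flag rather than lie", {
  fx <- tiny_surv_fixture(20, seed = 3)
  x2 <- cbind(fx$x, const = 1)
  expect_error(fit_cox(agingpanel:::new_cox_design(x2, fx$time, fx$event,
                                                   roles = c("gene", "gene"))),
               "constant")
  x3 <- cbind(a = fx$x[, 1], b = fx$x[, 1])
  expect_error(fit_cox(agingpanel:::new_cox_design(x3, fx$time, fx$event,
                                                   roles = c("gene", "gene"))),
               "duplicated")

  # complete separation: every event falls in one covariate group
  xs <- matrix(rep(c(0, 1), each = 6), ncol = 1, dimnames = list(NULL, "x"))
  sep <- agingpanel:::new_cox_design(xs, time = seq_len(12),
                                     event = rep(c(1L, 0L), each = 6), roles = "gene")
  f <- fit_cox(sep)
  expect_false(f$converged)
  expect_match(f$flag, "separation|iterations")
})

test_that("global Wald reduces to the per-term test for one term and is calibrated", {
  fx <- tiny_surv_fixture(40, seed = 13)
  f <- fit_cox(tiny_design(fx))
  w <- wald_global(f, "x")
  expect_equal(w$stat, unname(f$wald_z["x"])^2, tolerance = 1e-10)
  expect_equal(w$p, unname(f$wald_p["x"]), tolerance = 1e-12)
  expect_error(wald_global(f, character()), "nonempty")
  expect_error(wald_global(f, "phantom"), "phantom")

  # chi-square(3) calibration of the 3-gene global statistic under the null
  reps <- 400
  stats <- numeric(reps)
  base <- sim_config(n_samples = 60, n_genes = 6, gamma_grade = 0, gamma_age = 0,
                     censoring_target = 0.3, seed = 1)
  for (r in seq_len(reps)) {
    base$seed <- 9000 + r
    co <- simulate_cohort(base)$cohort
    genes <- cohort_genes(co)[1:3]
    f <- fit_cox(cox_design(co, genes))
    stats[r] <- f$global$stat
  }
  stats <- stats[is.finite(stats)]
  se_mean <- sqrt(6 / length(stats)) # var of chi-square(3) is 6
  expect_lt(abs(mean(stats) - 3), 3 * se_mean)
})

test_that("vif matches its closed forms and flags exact collinearity", {
  withr::with_seed(5, {
    q <- qr.Q(qr(cbind(1, matrix(rnorm(400), ncol = 4))))[, 2:5]
    colnames(q) <- paste0("v", 1:4)
    v <- vif(q)
    expect_true(all(abs(v$vif - 1) < 1e-10))

    n <- 10000
    z <- rnorm(n)
    x <- cbind(a = z, b = 0.6 * z + sqrt(1 - 0.36) * rnorm(n))
    v2 <- vif(x)
    expect_true(all(abs(v2$vif - 1.5625) / 1.5625 < 0.05))

    dup <- cbind(a = z[1:50], b = z[1:50])
    v3 <- vif(dup)
    expect_true(all(is.infinite(v3$vif)))
    expect_true(all(!v3$below_threshold))
  })
})

test_that("tidy and glance expose a complete, consistent fit summary", {
  sim <- simulate_cohort(sim_preset("pc_like", seed = 2))
  f <- fit_panel(sim$cohort, c("CD44", "GADD45B"), adjust_covariates = c("grade", "age"))
  td <- tidy(f)
  expect_equal(td$term, c("CD44", "GADD45B", "grade", "age"))
  expect_true(all(td$conf.low < td$hr & td$hr < td$conf.high))
  expect_true(all(td$hr > 0))
  gl <- glance(f)
  expect_equal(gl$global_df, 2)
  expect_gte(gl$loglik, gl$loglik_null)
  expect_true(gl$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
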