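test_that("a one-gene panel reduces to that gene's crude univariable fit", {
  co <- planted_cohort(n = 150, seed = 5)
  rec <- screen_genes(co, "CD44", adjust_covariates = character())
  f <- fit_panel(co, "CD44")
  expect_equal(unname(f$hr["CD44"]), rec$crude_hr[1], tolerance = 1e-10)
  expect_equal(f$global$p, rec$crude_p[1], tolerance = 1e-10)
})

test_that("fit_panel errors on empty panels and missing genes", {
  co <- planted_cohort(n = 100, seed = 6)
  expect_error(fit_panel(co, character()), "empty")
  expect_error(fit_panel(co, c("CD44", "GHOST")), "GHOST")
})

test_that("the planted additive panel is jointly significant at study scale", {
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    co <- planted_cohort(n = 300, seed = 700 + r)
    f <- fit_panel(co, c("CD44", "GADD45B", "STAT3", "GFAP"),
                   adjust_covariates = c("grade", "age"))
    if (f$converged && f$global$p < 1e-4) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("stratification rules partition the cohort exactly", {
  co <- planted_cohort(n = 200, seed = 31)
  for (spec in list(stratum_spec("grade"), stratum_spec("age", cutoff = 60))) {
    strata <- suppressMessages(stratify(co, spec))
    expect_equal(sum(vapply(strata, nrow, 0L)), nrow(co))
    expect_setequal(unlist(lapply(strata, `[[`, "sample_id")), co$sample_id)
  }
  # age cutoff below the cohort minimum leaves the younger stratum empty
  strata <- suppressMessages(stratify(co, stratum_spec("age", cutoff = min(co$age) - 1)))
  expect_equal(nrow(strata$younger), 0)
  expect_equal(nrow(strata$older), nrow(co))
})

test_that("published per-score Gleason counts reproduce the printed stratum sizes", {
  tab <- readr::read_tsv(system.file("extdata", "pc_gleason_distribution.tsv",
                                     package = "agingpanel"),
                         show_col_types = FALSE)
  expected <- list(Taylor = c(94, 44), TCGA = c(159, 225), DKFZ = c(68, 32))
  for (nm in names(expected)) {
    sub <- tab[tab$cohort == nm & tab$count > 0, ]
    co <- cohort_from_gleason_counts(sub$gleason, sub$count, name = nm)
    strata <- suppressMessages(stratify(co, stratum_spec("grade")))
    expect_equal(nrow(strata$low_grade), expected[[nm]][1], info = nm)
    expect_equal(nrow(strata$high_grade), expected[[nm]][2], info = nm)
  }
})

test_that("evaluate_strata flags empty/event-free strata and fits the rest", {
  co <- planted_cohort(n = 200, seed = 12)
  res <- evaluate_strata(co, c("CD44", "STAT3"),
                         list(stratum_spec("grade"),
                              stratum_spec("age", cutoff = min(co$age) - 1)))
  expect_equal(sum(res$n[res$axis == "grade"]), nrow(co))
  young <- res[res$axis == "age" & res$label == "younger", ]
  expect_false(young$analyzable)
  expect_true(is.na(young$global_wald_p))
  ok <- res[res$analyzable, ]
  expect_true(all(vapply(ok$fit, inherits, TRUE, what = "cox_fit")))
})

test_that("an all-inclusive stratum equals the whole-cohort panel fit", {
  co <- planted_cohort(n = 150, seed = 13)
  res <- evaluate_strata(co, c("CD44", "GFAP"),
                         stratum_spec("age", cutoff = max(co$age) + 1))
  whole <- fit_panel(co, c("CD44", "GFAP"))
  expect_equal(res$global_wald_p[res$label == "younger"], whole$global$p,
               tolerance = 1e-12)
})

test_that("a stratum-specific effect is detected where planted and not elsewhere", {
  # effect exists only in the high-grade stratum: simulate the two strata as
  # separate cohorts (beta = log .4 vs 0) and recombine
  hits_high <- hits_low <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    base <- list(n_genes = 60, gamma_grade = 0, gamma_age = 0,
                 censoring_target = 0.4, rho = 0.1)
    hi_cfg <- sim_config(n_samples = 200, n_genes = 60,
                         signal_genes = c(CD44 = log(0.4), GADD45B = log(0.4),
                                          STAT3 = log(0.4), GFAP = log(0.4)),
                         gamma_grade = 0, gamma_age = 0, censoring_target = 0.4,
                         grade_probs = c("4+4" = 1), seed = 2000 + r)
    lo_cfg <- sim_config(n_samples = 200, n_genes = 60,
                         gamma_grade = 0, gamma_age = 0, censoring_target = 0.4,
                         grade_probs = c("3+3" = 1), seed = 3000 + r)
    hi <- simulate_cohort(hi_cfg)$cohort
    lo <- simulate_cohort(lo_cfg)$cohort
    lo$sample_id <- paste0("L", lo$sample_id)
    both <- agingpanel:::as_cohort_like(dplyr::bind_rows(hi, lo), hi, name = "mix")
    res <- evaluate_strata(both, c("CD44", "GADD45B", "STAT3", "GFAP"),
                           stratum_spec("grade"))
    p_hi <- res$global_wald_p[res$label == "high_grade"]
    p_lo <- res$global_wald_p[res$label == "low_grade"]
    if (!is.na(p_hi) && p_hi < 0.05) hits_high <- hits_high + 1
    if (!is.na(p_lo) && p_lo > 0.05) hits_low <- hits_low + 1
  }
  expect_gte(hits_high / reps, 0.8)
  expect_gte(hits_low / reps, 0.8)
})

test_that("risk scores are the gene-term linear predictor", {
  co <- planted_cohort(n = 100, seed = 44)
  f <- fit_panel(co, c("CD44", "STAT3"), adjust_covariates = c("grade", "age"))
  rs <- risk_scores(co, f)
  manual <- as.matrix(co[, c("CD44", "STAT3")]) %*% f$beta[c("CD44", "STAT3")]
  expect_equal(rs$risk_score, drop(manual))
})
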