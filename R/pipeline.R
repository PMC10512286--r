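#' Build a run configuration
#'
#' One object drives the whole pipeline: which cohorts to load (or a
#' simulation preset per cohort), which one is the discovery cohort, the
#' candidate list, and the thresholds of every stage.
#'
#' @param cohorts Named list; each entry is either
#'   `list(expression = path, clinical = path, col_map = ..., transpose
#'   = FALSE, endpoint_label = ...)` for on-disk data or
#'   `list(preset = "pc_like", seed = n)` for a simulated cohort.
#' @param discovery Name of the discovery cohort (must be in `cohorts`).
#' @param candidates Candidate gene symbols, or a path to a plain-text
#'   file with one symbol per line.
#' @param alpha Screening significance level.
#' @param vif_threshold Panel multicollinearity cutoff.
#' @param adjust_covariates Adjustment covariates for screening and the
#'   full-cohort panel model.
#' @param age_cutoff Age stratification cutoff in years.
#' @param strat_axes Stratification axes among `"grade"`, `"age"`,
#'   `"risk"`.
#' @param family_size BH family size for integration (defaults to the
#'   number of strata produced by `strat_axes`).
#' @param null_R Repetitions for the random-panel null.
#' @param seed Master seed for simulated cohorts and the null model.
#' @param out_dir Optional output directory for [write_report()].
#' @return A `run_config` list.
#' @export
run_config <- function(cohorts, discovery, candidates = aging_candidate_genes(),
                       alpha = 0.05, vif_threshold = 5,
                       adjust_covariates = c("grade", "age"),
                       age_cutoff = 60, strat_axes = c("grade", "age"),
                       family_size = NULL, null_R = 1000L, seed = 1L,
                       out_dir = NULL) {
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    abort("every cohort entry must be named")
  if (!discovery %in% names(cohorts))
    abort(sprintf("unknown discovery cohort '%s'; cohorts: %s", discovery,
                  paste(names(cohorts), collapse = ", ")))
  if (is.character(candidates) && length(candidates) == 1L && file.exists(candidates))
    candidates <- readLines(candidates, warn = FALSE)
  candidates <- trimws(candidates)
  candidates <- candidates[nzchar(candidates)]
  if (length(candidates) == 0L) abort("candidate gene list is empty")
  bad_axes <- setdiff(strat_axes, c("grade", "age", "risk"))
  if (length(bad_axes) > 0L)
    abort(sprintf("unknown stratification axis: %s", paste(bad_axes, collapse = ", ")))
  structure(list(
    cohorts = cohorts, discovery = discovery, candidates = candidates,
    alpha = alpha, vif_threshold = vif_threshold,
    adjust_covariates = adjust_covariates, age_cutoff = age_cutoff,
    strat_axes = strat_axes, family_size = family_size,
    null_R = as.integer(null_R), seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
    file.path(base, p) else p
  y$cohorts <- lapply(y$cohorts, function(co) {
    co$expression <- rel(co$expression)
    co$clinical <- rel(co$clinical)
    co
  })
  if (!is.null(y$candidates)) y$candidates <- rel(y$candidates)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

# hash of the analysis-relevant configuration (output location excluded)
config_hash <- function(config) {
  cfg <- unclass(config)
  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
}

load_cohorts <- function(config) {
  out <- lapply(names(config$cohorts), function(nm) {
    entry <- config$cohorts[[nm]]
    if (!is.null(entry$preset)) {
      cfg <- sim_preset(entry$preset, seed = entry$seed %||% config$seed)
      sim <- simulate_cohort(cfg)
      cohort <- sim$cohort
      attr(cohort, "cohort_name") <- nm
      return(cohort)
    }
    expr <- read_expression(entry$expression, transpose = isTRUE(entry$transpose))
    clin <- read_clinical(entry$clinical, col_map = entry$col_map)
    assemble_cohort(expr, clin, name = nm,
                    endpoint_label = entry$endpoint_label %||% "time to event")
  })
  names(out) <- names(config$cohorts)
  out
}

config_specs <- function(config, cohort) {
  specs <- list()
  for (axis in config$strat_axes) {
    if (axis == "grade" && !"gleason_major" %in% names(cohort)) axis <- "risk"
    specs[[axis]] <- switch(axis,
      grade = stratum_spec("grade"),
      age = stratum_spec("age", cutoff = config$age_cutoff),
      risk = stratum_spec("risk")
    )
  }
  specs
}

#' Run the discovery stage
#'
#' Screen the candidates on the discovery cohort, select the panel,
#' fit the adjusted additive panel model, evaluate it within the
#' configured strata, and score every patient by the panel linear
#' predictor.
#'
#' @param config A `run_config`.
#' @param cohorts Optional preloaded cohort list (else loaded from the
#'   config).
#' @return List with `panel`, `screen`, `panel_fit`, `strata`,
#'   `risk_scores`; `panel_fit`/`strata`/`risk_scores` are `NULL` when
#'   the panel is empty.
#' @export
run_discovery <- function(config, cohorts = NULL) {
  cohorts <- cohorts %||% load_cohorts(config)
  disc <- cohorts[[config$discovery]]
  records <- screen_genes(disc, config$candidates,
                          adjust_covariates = config$adjust_covariates,
                          alpha = config$alpha)
  panel <- withCallingHandlers(
    select_panel(records, alpha = config$alpha,
                 vif_threshold = config$vif_threshold, cohort = disc),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (length(panel$genes) == 0L) {
    warn("discovery produced an empty panel; downstream stages will be skipped")
    return(list(panel = panel, screen = records, panel_fit = NULL,
                strata = NULL, risk_scores = NULL))
  }
  panel_fit <- fit_panel(disc, panel, adjust_covariates = config$adjust_covariates)
  strata <- evaluate_strata(disc, panel, config_specs(config, disc))
  list(panel = panel, screen = records, panel_fit = panel_fit,
       strata = strata,
       risk_scores = risk_scores(disc, panel_fit))
}

#' Run stratified validation of a panel on the non-discovery cohorts
#'
#' @param config A `run_config`.
#' @param panel The discovered `aging_panel`.
#' @param cohorts Optional preloaded cohort list.
#' @return Tibble of per-cohort stratum results (a `cohort` column plus
#'   the columns of [evaluate_strata()]).
#' @export
run_validation <- function(config, panel, cohorts = NULL) {
  if (length(panel_genes(panel)) == 0L) abort("cannot validate an empty panel")
  cohorts <- cohorts %||% load_cohorts(config)
  val_names <- setdiff(names(cohorts), config$discovery)
  purrr::map_dfr(val_names, function(nm) {
    co <- cohorts[[nm]]
    missing <- setdiff(panel_genes(panel), cohort_genes(co))
    if (length(missing) > 0L)
      abort(sprintf("cohort '%s' lacks panel gene(s): %s", nm,
                    paste(missing, collapse = ", ")))
    res <- evaluate_strata(co, panel, config_specs(config, co))
    single <- stats::aggregate(res$n > 0, by = list(axis = res$axis), FUN = sum)
    for (ax in single$axis[single$x < 2L])
      inform(sprintf("cohort '%s': axis '%s' has a single populated stratum", nm, ax))
    dplyr::bind_cols(tibble::tibble(cohort = nm), res)
  })
}

#' Run the full pipeline
#'
#' Discovery on the configured cohort, stratified validation on the
#' others, harmonic-mean + BH integration of the per-cohort stratum
#' p-values, and the random-gene-set null on the discovery cohort
#' (observed p = the crude additive panel model's global Wald p, matching
#' the crude random fits).
#'
#' @param config A `run_config`.
#' @return A `run_report` list with elements `version`, `seed`,
#'   `config_hash`, `screen`, `panel`, `panel_fit`, `strata`,
#'   `integration`, `null`, `risk_scores`. Written to `config$out_dir`
#'   when set (see [write_report()]).
#' @export
run_all <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  cohorts <- load_cohorts(config)
  stage_log <- function(stage, t_start)
    inform(sprintf("[%s] done in %.1fs (seed %d, config %s)", stage,
                   proc.time()[["elapsed"]] - t_start, config$seed,
                   substr(config_hash(config), 1, 8)))
  disc_name <- config$discovery

  t1 <- proc.time()[["elapsed"]]
  discovery <- run_discovery(config, cohorts = cohorts)
  stage_log("discovery", t1)

  strata_all <- NULL
  integration <- NULL
  nulldist <- NULL
  scores <- NULL
  if (length(discovery$panel$genes) > 0L) {
    t1 <- proc.time()[["elapsed"]]
    disc_res <- dplyr::bind_cols(tibble::tibble(cohort = disc_name), discovery$strata)
    val_res <- if (length(cohorts) > 1L)
      run_validation(config, discovery$panel, cohorts = cohorts) else NULL
    strata_all <- dplyr::bind_rows(disc_res, val_res)
    stage_log("validation", t1)

    t1 <- proc.time()[["elapsed"]]
    usable <- dplyr::filter(strata_all, .data$analyzable,
                            !is.na(.data$global_wald_p))
    if (nrow(usable) > 0L) {
      integration <- integrate_subgroups(
        tibble::tibble(subgroup = paste(usable$axis, usable$label, sep = ":"),
                       cohort = usable$cohort, p = usable$global_wald_p),
        family_size = config$family_size
      )
    }
    stage_log("integration", t1)

    t1 <- proc.time()[["elapsed"]]
    crude_fit <- fit_panel(cohorts[[disc_name]], discovery$panel)
    nulldist <- random_panel_null(
      cohorts[[disc_name]], k = length(discovery$panel$genes),
      R = config$null_R, observed_p = crude_fit$global$p,
      seed = config$seed
    )
    stage_log("random-null", t1)

    scores <- purrr::map_dfr(names(cohorts), function(nm)
      dplyr::bind_cols(tibble::tibble(cohort = nm),
                       risk_scores(cohorts[[nm]], discovery$panel_fit)))
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("agingpanel")),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    screen = tibble::as_tibble(discovery$screen),
    missing_genes = attr(discovery$screen, "missing_genes"),
    panel = discovery$panel,
    panel_fit = discovery$panel_fit,
    strata = strata_all,
    integration = integration,
    null = nulldist,
    risk_scores = scores
  ), class = "run_report")
  stage_log("run-all", t0)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

# Human-readable summary; every number is read off the report fields.
render_summary <- function(report) {
  out <- c(
    sprintf("agingpanel run report (version %s, seed %d, config %s)",
            report$version, report$seed, substr(report$config_hash, 1, 8)),
    sprintf("Screened %d candidate gene(s); %d missing from expression data.",
            nrow(report$screen), length(report$missing_genes)),
    sprintf("Panel: %s", if (length(report$panel$genes) == 0L) "<empty>"
            else paste(report$panel$genes, collapse = ", "))
  )
  if (!is.null(report$panel_fit)) {
    g <- report$panel_fit$global
    out <- c(out, sprintf(
      "Adjusted additive panel model: global Wald chi-square = %.4g (df %d), p = %.4g",
      g$stat, g$df, g$p))
  }
  if (!is.null(report$strata)) {
    s <- report$strata
    out <- c(out, "Stratified panel models:",
             sprintf("  %s / %s:%s n=%d events=%d p=%s", s$cohort, s$axis, s$label,
                     s$n, s$n_events, ifelse(is.na(s$global_wald_p), "NA",
                                             sprintf("%.4g", s$global_wald_p))))
  }
  if (!is.null(report$integration)) {
    i <- report$integration
    out <- c(out, "Cross-cohort integration (harmonic mean + BH):",
             sprintf("  %s: raw = %.4g, FDR-adjusted = %.4g (m = %d)",
                     i$subgroup, i$raw_integrated_p, i$fdr_adjusted_p, i$m))
  }
  if (!is.null(report$null)) {
    out <- c(out, sprintf(
      "Random %d-gene null: R = %d, observed p = %.3g, nominal p = %.4g",
      report$null$k, report$null$R, report$null$observed_p, report$null$nominal_p))
  }
  out
}

#' Write a run report to disk
#'
#' Writes `report.json` (the full machine-readable report), TSVs of the
#' screening records, stratum results, integration results and risk
#' scores, the random-null p sample, and `summary.txt` rendered from the
#' report fields alone. Output is byte-identical for identical config +
#' seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    version = report$version, seed = report$seed,
    config_hash = report$config_hash,
    screen = report$screen, missing_genes = report$missing_genes,
    panel = list(genes = report$panel$genes, alpha = report$panel$alpha,
                 vif = report$panel$vif,
                 cohort = report$panel$cohort_name),
    panel_fit = if (!is.null(report$panel_fit)) list(
      terms = tidy(report$panel_fit), model = glance(report$panel_fit)),
    strata = if (!is.null(report$strata))
      dplyr::select(report$strata, -"fit"),
    integration = if (!is.null(report$integration))
      dplyr::select(report$integration, -"cohort_ps"),
    null = if (!is.null(report$null)) glance(report$null),
    risk_scores = report$risk_scores
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(report$screen, file.path(dir, "screen_records.tsv"), progress = FALSE)
  if (!is.null(report$strata))
    readr::write_tsv(dplyr::select(report$strata, -"fit"),
                     file.path(dir, "stratum_results.tsv"), progress = FALSE)
  if (!is.null(report$integration))
    readr::write_tsv(dplyr::select(report$integration, -"cohort_ps"),
                     file.path(dir, "integration.tsv"), progress = FALSE)
  if (!is.null(report$null))
    readr::write_tsv(tidy(report$null), file.path(dir, "random_null_ps.tsv"),
                     progress = FALSE)
  if (!is.null(report$risk_scores))
    readr::write_tsv(report$risk_scores, file.path(dir, "risk_scores.tsv"),
                     progress = FALSE)
  writeLines(render_summary(report), file.path(dir, "summary.txt"))
  invisible(dir)
}
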