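#' Read a normalized gene-expression matrix
#'
#' Expression files are tab-delimited with genes in rows (the GEO
#' series-matrix convention): a header line naming the samples, a first
#' column of gene symbols, and one numeric column per sample on whatever
#' normalized scale the upstream pipeline produced (log2, variance
#' stabilized, or z-scored). Use `transpose = TRUE` for files with samples
#' in rows.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is samples x genes and is
#'   transposed on read.
#' @return A numeric matrix, genes in rows, with unique row (gene) and
#'   column (sample) names.
#' @export
read_expression <- function(path, transpose = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2L) abort("expression file needs a gene column plus at least one sample")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-numeric expression value '%s' at row %d (gene '%s'), column '%s'",
      vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
      colnames(vals)[bad[1L, 2L]]
    ))
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  validate_expression(num)
  num
}

validate_expression <- function(mat) {
  genes <- rownames(mat)
  samples <- colnames(mat)
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene symbol(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  if (any(!is.finite(mat))) abort("expression matrix contains non-finite values")
  invisible(mat)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values round-trip to at least 12
#' significant digits and row/column order is preserved.
#'
#' @param mat Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Clinical tables are CSV with one row per sample carrying the follow-up
#' time (months), the event flag (1 = event, 0 = censored), chronological
#' age (years), and the grade encoding: either a Gleason score (as
#' `gleason_major`/`gleason_minor` columns, or a single `gleason` column
#' with "major+minor" strings such as "4+3") or a cytogenetic
#' `risk_category` (favorable / unfavorable). Column names in the file are
#' mapped to these standard names through `col_map`. Rows missing any
#' required field are dropped with a reported count.
#'
#' @param path Path to a CSV file.
#' @param col_map Named character vector or list mapping standard names
#'   (`sample_id`, `time`, `event`, `age`, and one grade encoding) to the
#'   column names used in the file. Standard names are assumed where
#'   omitted.
#' @return A tibble with columns `sample_id`, `time`, `event`, `age`, and
#'   either `gleason_major` + `gleason_minor` or `risk_category`.
#' @export
read_clinical <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  std <- c("sample_id", "time", "event", "age", "gleason", "gleason_major",
           "gleason_minor", "risk_category")
  map <- stats::setNames(std, std)
  if (!is.null(col_map)) {
    col_map <- unlist(col_map)
    unknown <- setdiff(names(col_map), std)
    if (length(unknown) > 0L)
      abort(sprintf("unknown clinical field(s) in col_map: %s", paste(unknown, collapse = ", ")))
    map[names(col_map)] <- col_map
  }
  get <- function(field) if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NULL

  out <- tibble::tibble(sample_id = get("sample_id"))
  if (is.null(out$sample_id)) abort("clinical table lacks a sample id column")
  out$time <- suppressWarnings(as.numeric(get("time") %||% abort("clinical table lacks a time column")))
  out$event <- suppressWarnings(as.numeric(get("event") %||% abort("clinical table lacks an event column")))
  out$age <- suppressWarnings(as.numeric(get("age") %||% abort("clinical table lacks an age column")))

  gl <- get("gleason")
  gm <- get("gleason_major")
  gn <- get("gleason_minor")
  rc <- get("risk_category")
  has_gleason <- !is.null(gl) || (!is.null(gm) && !is.null(gn))
  if (has_gleason && !is.null(rc))
    abort("clinical table must use exactly one grade encoding (Gleason or risk category)")
  if (!has_gleason && is.null(rc))
    abort("clinical table lacks a grade encoding (Gleason or risk category)")

  if (has_gleason) {
    if (!is.null(gl)) {
      parts <- strsplit(trimws(gl), "\\s*\\+\\s*")
      out$gleason_major <- suppressWarnings(as.integer(vapply(parts, function(x) x[1L], "")))
      out$gleason_minor <- suppressWarnings(as.integer(vapply(parts, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")))
    } else {
      out$gleason_major <- suppressWarnings(as.integer(gm))
      out$gleason_minor <- suppressWarnings(as.integer(gn))
    }
    grade_ok <- !is.na(out$gleason_major) & !is.na(out$gleason_minor)
  } else {
    rc <- tolower(trimws(rc))
    rc[!rc %in% c("favorable", "unfavorable")] <- NA_character_
    out$risk_category <- rc
    grade_ok <- !is.na(out$risk_category)
  }

  neg <- which(!is.na(out$time) & out$time <= 0)
  if (length(neg) > 0L)
    abort(sprintf("non-positive follow-up time for sample(s): %s",
                  paste(out$sample_id[neg], collapse = ", ")))
  bad_event <- which(!is.na(out$event) & !out$event %in% c(0, 1))
  if (length(bad_event) > 0L)
    abort(sprintf("event flag not in {0,1} for sample(s): %s",
                  paste(out$sample_id[bad_event], collapse = ", ")))

  keep <- !is.na(out$sample_id) & !is.na(out$time) & !is.na(out$event) &
    !is.na(out$age) & grade_ok
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    inform(sprintf("read_clinical: dropped %d of %d rows with missing fields", n_drop, nrow(out)))
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("clinical table has no usable rows")
  if (anyDuplicated(out$sample_id))
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", ")))
  out$event <- as.integer(out$event)
  out
}

#' Write a clinical table as CSV
#'
#' @param clinical Tibble as returned by [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Assemble a cohort from expression and clinical data
#'
#' Inner-joins the two inputs on sample id and returns a samples x
#' variables tibble: one row per sample, the clinical fields, a numeric
#' `grade` adjustment covariate (Gleason major + minor sum, or cytogenetic
#' risk coded 0 = favorable / 1 = unfavorable), and one column per gene.
#' Sample order is deterministic (sorted by sample id).
#'
#' @param expr Numeric expression matrix, genes in rows.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param name Cohort name.
#' @param endpoint_label Free-text label for the time-to-event endpoint
#'   (e.g. "time to BCR", "overall survival").
#' @return An `aging_cohort` tibble. Gene columns are listed in
#'   `cohort_genes()`; the cohort name, endpoint and grade encoding are
#'   carried as attributes.
#' @export
assemble_cohort <- function(expr, clinical, name, endpoint_label = "time to event") {
  validate_expression(expr)
  shared <- sort(intersect(colnames(expr), clinical$sample_id))
  if (length(shared) == 0L) abort("no shared sample ids between expression and clinical data")
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  if (sum(clin$event) == 0L) abort("cohort has zero events after joining")

  grade_type <- if ("risk_category" %in% names(clin)) "risk" else "gleason"
  grade <- if (grade_type == "risk") {
    as.numeric(clin$risk_category == "unfavorable")
  } else {
    as.numeric(clin$gleason_major + clin$gleason_minor)
  }
  out <- dplyr::bind_cols(
    clin, tibble::tibble(grade = grade),
    tibble::as_tibble(t(expr[, shared, drop = FALSE]))
  )
  new_cohort(out, name = name, genes = rownames(expr), grade_type = grade_type,
             endpoint_label = endpoint_label)
}

new_cohort <- function(df, name, genes, grade_type, endpoint_label) {
  structure(
    tibble::new_tibble(df, nrow = nrow(df)),
    cohort_name = name, genes = genes, grade_type = grade_type,
    endpoint_label = endpoint_label,
    class = c("aging_cohort", class(tibble::tibble()))
  )
}

#' @export
print.aging_cohort <- function(x, ...) {
  cat(sprintf("# Cohort '%s': %d samples, %d events, %d genes (%s grading; %s)\n",
              cohort_name(x), nrow(x), sum(x$event), length(cohort_genes(x)),
              attr(x, "grade_type"), attr(x, "endpoint_label")))
  NextMethod()
}

#' Cohort accessors
#'
#' @param cohort An `aging_cohort`.
#' @return `cohort_genes()`: character vector of gene columns;
#'   `cohort_name()`: the cohort's name.
#' @export
cohort_genes <- function(cohort) attr(cohort, "genes")

#' @rdname cohort_genes
#' @export
cohort_name <- function(cohort) attr(cohort, "cohort_name")

as_cohort_like <- function(df, template, name = cohort_name(template)) {
  new_cohort(df, name = name, genes = cohort_genes(template),
             grade_type = attr(template, "grade_type"),
             endpoint_label = attr(template, "endpoint_label"))
}

#' Z-score each gene across samples
#'
#' Centers and scales every gene row to mean 0 and sample SD 1, the scale
#' on which per-unit hazard ratios are comparable across genes.
#' Zero-variance genes are left unscaled with a warning naming them.
#'
#' @param expr Numeric expression matrix, genes in rows (>= 2 samples).
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(expr) {
  if (ncol(expr) < 2L) abort("z-scoring needs at least 2 samples")
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    warn(sprintf("zscore_genes: %d zero-variance gene(s) left unscaled: %s",
                 sum(flat), paste(head(rownames(expr)[flat], 5L), collapse = ", ")))
  }
  scale_to <- ifelse(flat, 1, s)
  center_to <- ifelse(flat, 0, mu)
  out <- (expr - center_to) / scale_to
  dimnames(out) <- dimnames(expr)
  out
}
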