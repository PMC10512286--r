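test_that("expression TSV round-trips values, ids and order", {
  mat <- matrix(c(1.25, -0.5, 3.75, 2, 0.1, -9.125, 7, 0.5, 1e-3, pi, exp(1), sqrt(2)),
                nrow = 3, dimnames = list(c("GENEB", "GENEA", "GENEC"),
                                          c("S1", "S2", "S3", "S4")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, path)
  back <- read_expression(path)
  expect_identical(dim(back), c(3L, 4L))
  expect_identical(rownames(back), rownames(mat)) # order preserved, not sorted
  expect_identical(colnames(back), colnames(mat))
  expect_equal(back, mat, tolerance = 1e-12)
})

test_that("simulated cohort expression survives a write/read cycle to 12 digits", {
  sim <- simulate_cohort(sim_config(n_samples = 20, n_genes = 40, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_expression(file.path(dir, "expression.tsv"))
  orig <- t(as.matrix(sim$cohort[, cohort_genes(sim$cohort)]))
  colnames(orig) <- sim$cohort$sample_id
  expect_equal(back, orig, tolerance = 1e-12)
  clin <- suppressMessages(read_clinical(file.path(dir, "clinical.csv")))
  expect_equal(nrow(clin), 20)
})

test_that("malformed expression input fails with a named hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "TP53\t1\t2", "TP53\t3\t4"), path)
  expect_error(read_expression(path), "TP53")

  writeLines(c("gene\tS1\tS2", "TP53\t1\toops", "BRCA1\t3\t4"), path)
  expect_error(read_expression(path), "oops")
})

test_that("clinical parsing drops incomplete rows with a count and rejects bad times", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = sprintf("S%02d", 1:10), time = 1:10,
                   event = rep(c(0, 1), 5), age = c(NA, 60:67, NA),
                   gleason = "4+3")
  readr::write_csv(df, path)
  expect_message(clin <- read_clinical(path), "dropped 2 of 10")
  expect_equal(nrow(clin), 8)
  expect_equal(unique(clin$gleason_major), 4L)
  expect_equal(unique(clin$gleason_minor), 3L)

  df$age <- 60
  df$time[3] <- -1
  readr::write_csv(df, path)
  expect_error(read_clinical(path), "S03")

  # zero follow-up time is rejected, not guessed at
  df$time[3] <- 0
  readr::write_csv(df, path)
  expect_error(read_clinical(path), "S03")
})

test_that("clinical column mapping and risk encoding work", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(id = c("A", "B"), os_months = c(12, 30),
                              dead = c(1, 0), years = c(50, 70),
                              eln = c("Favorable", "unfavorable")), path)
  clin <- read_clinical(path, col_map = list(sample_id = "id", time = "os_months",
                                             event = "dead", age = "years",
                                             risk_category = "eln"))
  expect_equal(clin$risk_category, c("favorable", "unfavorable"))
  expect_error(read_clinical(path, col_map = list(banana = "id")), "banana")
})

test_that("assemble_cohort inner-joins on sorted sample ids", {
  expr <- matrix(rnorm(9), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("C", "A", "B")))
  clin <- tibble::tibble(sample_id = c("B", "C", "D"), time = c(5, 8, 2),
                         event = c(1L, 0L, 1L), age = c(60, 62, 58),
                         gleason_major = 3L, gleason_minor = 4L)
  co <- assemble_cohort(expr, clin, name = "toy")
  expect_s3_class(co, "aging_cohort")
  expect_identical(co$sample_id, c("B", "C")) # intersection, sorted
  expect_equal(co$grade, c(7, 7))
  expect_equal(co$G2[co$sample_id == "B"], expr["G2", "B"])

  clin_disjoint <- dplyr::mutate(clin, sample_id = c("X", "Y", "Z"))
  expect_error(assemble_cohort(expr, clin_disjoint, "toy"), "no shared sample")
  clin_noevent <- dplyr::mutate(clin, event = 0L)
  expect_error(assemble_cohort(expr, clin_noevent, "toy"), "zero events")
})

test_that("cohort assembly round-trips the simulated sample size", {
  sim <- simulate_cohort(sim_config(n_samples = 37, n_genes = 30, seed = 9))
  expect_equal(nrow(sim$cohort), 37)
  expect_length(cohort_genes(sim$cohort), 30)
})

test_that("zscore_genes standardizes rows and flags constant genes", {
  expect_equal(unname(zscore_genes(matrix(c(1, 2, 3), nrow = 1,
                                          dimnames = list("g", NULL)))[1, ]),
               c(-1, 0, 1))

  m <- matrix(rnorm(50 * 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  z <- zscore_genes(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))

  m[7, ] <- 4.2
  expect_warning(z2 <- zscore_genes(m), "g07")
  expect_equal(unname(z2[7, ]), rep(4.2, 20)) # left unscaled
})
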