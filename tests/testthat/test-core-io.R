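test_that("beta matrix construction validates ids and value bounds", {
  m <- matrix(c(0.1, 0.9, 0.5, 0.4, NA, 0.2), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  bm <- beta_matrix(m)
  expect_identical(dim(bm), c(3L, 2L))
  expect_identical(probe_ids(bm), c("cg1", "cg2", "cg3"))

  m_bad <- m
  m_bad["cg2", "s1"] <- 1.2
  expect_error(beta_matrix(m_bad), "cg2.*s1|1\\.2")

  m_dup <- m
  rownames(m_dup) <- c("cg1", "cg1", "cg3")
  expect_error(beta_matrix(m_dup), "duplicate probe")

  expect_error(
    beta_matrix(m, detection_p = matrix(0.001, 2, 2)),
    "same shape")
})

test_that("beta matrix TSV round-trip is lossless and orientation-aware", {
  bm <- random_beta_matrix(8, 5, seed = 1, missing = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, path)
  back <- read_beta_matrix(path)
  expect_identical(back$values, bm$values)

  # transposed writing reads back to the same probes-as-rows object
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, path2, orientation = "samples_rows")
  back2 <- read_beta_matrix(path2, orientation = "samples_rows")
  expect_identical(back2$values, bm$values)

  # reading the transposed file as probes_rows yields the transpose
  flipped <- read_beta_matrix(path2, orientation = "probes_rows")
  expect_identical(flipped$values, t(bm$values))
})

test_that("detection p-values survive a TSV round-trip alongside betas", {
  m <- random_beta_matrix(4, 3, seed = 5)$values
  detp <- matrix(runif(12, 0, 0.05), 4, 3, dimnames = dimnames(m))
  bm <- beta_matrix(m, detection_p = detp)
  path <- withr::local_tempfile(fileext = ".tsv")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, path, detection_p_path = dpath)
  back <- read_beta_matrix(path, detection_p_path = dpath)
  expect_identical(back$detection_p, detp)
})

test_that("clock files parse the (Intercept) sentinel and drop zero rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,coefficient", "(Intercept),280", "cg1,10", "cg2,-5",
               "cg3,0"), path)
  clock <- read_clock_file(path)
  expect_equal(clock$intercept, 280)
  expect_equal(clock$coefficients, c(cg1 = 10, cg2 = -5))
  expect_false("cg3" %in% names(clock$coefficients))

  writeLines(c("term,coefficient", "cg1,10"), path)
  expect_error(read_clock_file(path), "Intercept")
  writeLines(c("term,coefficient", "(Intercept),280", "cg1,abc"), path)
  expect_error(read_clock_file(path), "coefficient")
})

test_that("clock CSV round-trip reproduces coefficients exactly", {
  clock <- random_clock(n_cpgs = 12, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clock_file(clock, path)
  back <- read_clock_file(path)
  expect_identical(back$intercept, clock$intercept)
  expect_identical(back$coefficients, clock$coefficients)
  expect_identical(back$training_medians[names(back$coefficients)],
                   clock$training_medians[names(clock$coefficients)])
})

test_that("sample sheets round-trip through CSV with schema validation", {
  cohort <- simulate_cohort(sim_config(n_samples = 25, n_probes = 10,
                                       n_active = 2, seed = 9))
  sheet <- cohort$samples
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, path)
  back <- read_sample_sheet(path)
  expect_equal(as.data.frame(back), as.data.frame(sheet))
})

test_that("sample sheet validation rejects inconsistent records", {
  base <- tibble::tibble(
    sample_id = "s1", ga_ultrasound_days = 280L, art = TRUE,
    procedure = "IVF", embryo_state = "fresh",
    birth_date = as.Date("2010-09-23"),
    egg_retrieval_date = as.Date("2010-01-01"),
    embryo_insertion_date = as.Date("2010-01-03"),
    freeze_date = as.Date(NA), ga_etd_days = NA_integer_)
  expect_silent(as_sample_sheet(base))

  bad_order <- base
  bad_order$embryo_insertion_date <- as.Date("2009-12-01")
  expect_error(as_sample_sheet(bad_order), "date order")

  leak <- base
  leak$art <- FALSE
  expect_error(as_sample_sheet(leak), "non-ART")

  neg <- base
  neg$ga_ultrasound_days <- 0L
  expect_error(as_sample_sheet(neg), "non-positive")
})

test_that("probe lists round-trip as plain text", {
  ids <- sprintf("cg%05d", 1:7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_probe_list(ids, path)
  expect_identical(read_probe_list(path), ids)
})
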