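test_that("the three date rules reproduce constructed examples exactly", {
  # fresh transfer with a known retrieval date: (birth - retrieval) + 14
  fresh <- art_record(retrieval = as.Date("2010-01-01"),
                      birth = as.Date("2010-09-23"))
  expect_identical(compute_etd_ga(fresh), 279L)

  # fresh without retrieval: insertion stands in, minus two culture days
  no_retrieval <- art_record(retrieval = as.Date(NA),
                             insertion = as.Date("2010-01-03"),
                             birth = as.Date("2010-09-23"))
  expect_identical(compute_etd_ga(no_retrieval), 279L)

  # frozen: (birth - insertion) + 14 + days from retrieval to freezing
  frozen <- art_record(embryo_state = "frozen",
                       retrieval = as.Date("2010-01-01"),
                       freeze = as.Date("2010-01-06"),
                       insertion = as.Date("2010-03-01"),
                       birth = as.Date("2010-11-16"))
  expect_identical(compute_etd_ga(frozen), 279L)
})

test_that("the two fresh rules agree when insertion is retrieval + 2", {
  rec <- art_record()
  with_retrieval <- compute_etd_ga(rec)
  rec$egg_retrieval_date <- as.Date(NA)
  expect_identical(compute_etd_ga(rec), with_retrieval)
})

test_that("ETD is invariant to shifting every date by the same offset", {
  recs <- list(art_record(),
               art_record(embryo_state = "frozen",
                          retrieval = as.Date("2010-01-01"),
                          freeze = as.Date("2010-01-05"),
                          insertion = as.Date("2010-04-01"),
                          birth = as.Date("2010-12-10")))
  for (rec in recs) {
    base <- compute_etd_ga(rec)
    for (shift in c(-100L, 37L, 365L)) {
      shifted <- rec
      for (f in c("birth_date", "egg_retrieval_date",
                  "embryo_insertion_date", "freeze_date")) {
        if (!is.na(shifted[[f]])) shifted[[f]] <- shifted[[f]] + shift
      }
      expect_identical(compute_etd_ga(shifted), base)
    }
  }
})

test_that("non-ART records and insufficient dates are rejected by name", {
  rec <- art_record()
  rec$art <- FALSE
  expect_error(compute_etd_ga(rec), "ART records only")

  no_dates <- art_record(retrieval = as.Date(NA), insertion = as.Date(NA))
  expect_error(compute_etd_ga(no_dates), "egg_retrieval_date")

  frozen_missing <- art_record(embryo_state = "frozen", freeze = as.Date(NA))
  expect_error(compute_etd_ga(frozen_missing), "freeze_date")

  negative <- art_record(retrieval = as.Date("2010-01-01"),
                         insertion = as.Date("2010-01-03"),
                         birth = as.Date("2009-12-01"))
  expect_error(compute_etd_ga(negative), "non-positive")
})

test_that("annotate_etd recovers the simulator's true GA for ART samples", {
  cfg <- sim_config(n_samples = 120, n_probes = 5, n_active = 0, seed = 43,
                    art_fraction = 0.5, frozen_fraction = 0.3)
  co <- simulate_cohort(cfg)
  sheet <- annotate_etd(co$samples)
  art <- sheet$art
  expect_identical(as.integer(sheet$ga_etd_days[art]),
                   unname(co$truth$true_ga_days[sheet$sample_id[art]]))
  expect_true(all(is.na(sheet$ga_etd_days[!art])))
  report <- attr(sheet, "etd_report")
  expect_equal(nrow(report), sum(art))
  expect_setequal(unique(report$rule), c("fresh_retrieval", "frozen"))
})

test_that("a date-deficient record is flagged while the rest annotate", {
  cfg <- sim_config(n_samples = 30, n_probes = 5, n_active = 0, seed = 47,
                    art_fraction = 0.5)
  sheet <- simulate_cohort(cfg)$samples
  victim <- which(sheet$art)[1]
  sheet$egg_retrieval_date[victim] <- NA
  sheet$embryo_insertion_date[victim] <- NA
  out <- annotate_etd(sheet)
  report <- attr(out, "etd_report")
  expect_identical(report$rule[report$sample_id == sheet$sample_id[victim]],
                   "failed")
  expect_true(is.na(out$ga_etd_days[victim]))
  others <- setdiff(which(out$art), victim)
  expect_false(anyNA(out$ga_etd_days[others]))
})

test_that("an all-non-ART sheet passes through unchanged", {
  cfg <- sim_config(n_samples = 20, n_probes = 5, n_active = 0, seed = 49,
                    art_fraction = 0)
  sheet <- simulate_cohort(cfg)$samples
  out <- annotate_etd(sheet)
  expect_true(all(is.na(out$ga_etd_days)))
  expect_equal(nrow(attr(out, "etd_report")), 0)
})
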