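test_that("train/test splits have forced sizes and are seeded", {
  ids <- sprintf("s%03d", 1:10)
  sp <- split_train_test(ids, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, 0.8, seed = 1))
  expect_error(split_train_test("s1", 0.8, 1), "at least two")
  expect_error(split_train_test(ids, 1.0, 1), "strictly between")
})

test_that("every sample lands in training at about the configured rate", {
  ids <- sprintf("s%04d", 1:200)
  in_train <- matrix(FALSE, 200, 100)
  for (s in 1:100) {
    in_train[, s] <- ids %in% split_train_test(ids, 0.8, seed = s)$train
  }
  rate <- rowMeans(in_train)
  expect_equal(mean(rate), 0.8, tolerance = 0.001)  # exact by construction
  expect_true(all(rate > 0.6 & rate < 0.95))
})

test_that("a noise-free single-active-probe cohort trains to that probe", {
  cfg <- sim_config(n_samples = 60, n_probes = 40, n_active = 1,
                    effect_sd = 0.02, noise_sd = 0, art_fraction = 0,
                    seed = 19, missing_rate = 0)
  co <- simulate_cohort(cfg)
  clock <- train_clock(co$beta, co$samples, train_config(n_folds = 5, seed = 19))
  expect_true(co$truth$active_probe_ids %in% names(clock$coefficients))
})

test_that("training is reproducible and records metadata and medians", {
  cfg <- sim_config(n_samples = 80, n_probes = 150, n_active = 10,
                    signal_fraction = 0.8, seed = 23, missing_rate = 0.01)
  co <- simulate_cohort(cfg)
  tc <- train_config(n_folds = 5, seed = 29)
  a <- train_clock(co$beta, co$samples, tc)
  b <- train_clock(co$beta, co$samples, tc)
  expect_identical(a$coefficients, b$coefficients)
  expect_identical(a$lambda, b$lambda)
  expect_equal(a$alpha, 1)
  expect_equal(a$n_folds, 5L)
  expect_setequal(names(a$training_medians), names(a$coefficients))
})

test_that("ETD-sourced training requires ART samples with ETD dates", {
  cfg <- sim_config(n_samples = 60, n_probes = 50, n_active = 5,
                    art_fraction = 0.5, seed = 31)
  co <- simulate_cohort(cfg)
  sheet <- annotate_etd(co$samples)
  expect_error(train_clock(co$beta, sheet, train_config(n_folds = 5, seed = 1),
                           ga_source = "etd"),
               "ART samples only")
  art_ids <- sheet$sample_id[sheet$art]
  bm_art <- subset_beta(co$beta, samples = art_ids)
  clock <- train_clock(bm_art, sheet, train_config(n_folds = 5, seed = 1),
                       ga_source = "etd")
  expect_s3_class(clock, "ga_clock")
})

test_that("prediction is the stated linear combination", {
  clock <- ga_clock(280, c(cg1 = 10, cg2 = -5),
                    training_medians = c(cg1 = 0.5, cg2 = 0.2))
  m <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
  expect_equal(predict_ga(beta_matrix(m), clock)$ga_dnam_days, 284,
               tolerance = 1e-13)

  # empty clock predicts the intercept everywhere
  empty <- ga_clock(275, stats::setNames(numeric(0), character(0)))
  bm <- random_beta_matrix(4, 3, seed = 2)
  expect_equal(predict_ga(bm, empty)$ga_dnam_days, rep(275, 3))
})

test_that("predictions equal a brute-force dot product on random inputs", {
  withr::with_seed(37, {
    for (rep in 1:5) {
      bm <- random_beta_matrix(30, 8, seed = 400 + rep)
      ids <- sample(probe_ids(bm), 10)
      clock <- ga_clock(runif(1, 250, 300),
                        stats::setNames(rnorm(10, 0, 30), ids))
      pred <- predict_ga(bm, clock)
      for (s in seq_len(8)) {
        manual <- clock$intercept +
          sum(clock$coefficients * bm$values[ids, s])
        expect_equal(pred$ga_dnam_days[s], manual, tolerance = 1e-13)
      }
    }
  })
})

test_that("prediction is invariant to probe order and sample permutation", {
  bm <- random_beta_matrix(20, 6, seed = 51)
  ids <- probe_ids(bm)[3:8]
  clock <- ga_clock(280, stats::setNames(seq(-10, 15, by = 5), ids))
  pred <- predict_ga(bm, clock)

  shuf_p <- beta_matrix(bm$values[rev(probe_ids(bm)), ])
  expect_equal(predict_ga(shuf_p, clock)$ga_dnam_days, pred$ga_dnam_days,
               tolerance = 1e-13)

  perm <- c(4, 1, 6, 2, 3, 5)
  shuf_s <- beta_matrix(bm$values[, perm])
  pred_s <- predict_ga(shuf_s, clock)
  expect_identical(pred_s$sample_id, pred$sample_id[perm])
  expect_equal(pred_s$ga_dnam_days, pred$ga_dnam_days[perm])
})

test_that("absent clock probes are median-imputed or excluded with a count", {
  bm <- random_beta_matrix(5, 4, seed = 61)
  present <- probe_ids(bm)[1:2]
  coefs <- stats::setNames(c(10, -5, 8), c(present, "cg_gone"))
  meds <- stats::setNames(c(0.5, 0.2, 0.3), names(coefs))
  clock <- ga_clock(280, coefs, training_medians = meds)
  pred <- predict_ga(bm, clock)
  expect_identical(attr(pred, "absent_probes"), "cg_gone")
  expect_identical(attr(pred, "excluded_probes"), character(0))
  manual <- 280 + as.numeric(crossprod(bm$values[present, ], coefs[present])) +
    8 * 0.3
  expect_equal(pred$ga_dnam_days, manual, tolerance = 1e-13)

  # same clock without medians: the absent probe is excluded instead
  clock2 <- ga_clock(280, coefs)
  pred2 <- predict_ga(bm, clock2)
  expect_identical(attr(pred2, "excluded_probes"), "cg_gone")
  expect_equal(pred2$ga_dnam_days, manual - 8 * 0.3, tolerance = 1e-13)

  # probe present but missing for one sample: dataset median imputation
  v <- bm$values
  v[present[1], 2] <- NA
  pred3 <- predict_ga(beta_matrix(v), clock)
  med <- stats::median(v[present[1], ], na.rm = TRUE)
  manual3 <- 280 + coefs[1] * med + coefs[2] * v[present[2], 2] + 8 * 0.3
  expect_equal(pred3$ga_dnam_days[2], unname(manual3), tolerance = 1e-13)

  expect_error(predict_ga(bm, ga_clock(280, c(cg_zzz = 5))), "none of the")
})
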