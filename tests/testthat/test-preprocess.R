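ann_all_clear <- function(bm) {
  tibble::tibble(probe_id = probe_ids(bm), on_450k = TRUE,
                 cross_reactive = FALSE, snp_overlap = FALSE, autosomal = TRUE)
}

test_that("filtering with no flags and no detection grid is the identity", {
  bm <- random_beta_matrix(20, 6, seed = 3)
  res <- filter_probes(bm, ann_all_clear(bm))
  expect_identical(res$beta$values, bm$values)
  expect_identical(res$report$n_removed, rep(0L, 4))
})

test_that("planted disjoint flags give forced stage counts", {
  bm <- random_beta_matrix(100, 4, seed = 8)
  ann <- ann_all_clear(bm)
  ann$cross_reactive[1:10] <- TRUE
  ann$snp_overlap[16:18] <- TRUE
  detp <- matrix(0.001, 100, 4, dimnames = dimnames(bm$values))
  detp[11:15, 2] <- 0.5  # five probes fail in one sample
  bm <- beta_matrix(bm$values, detection_p = detp)
  res <- filter_probes(bm, ann)
  expect_identical(res$report$n_removed, c(10L, 5L, 3L, 0L))
  expect_equal(nrow(res$beta), 82)
})

test_that("overlapping flags match an order-respecting set-algebra recount", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n_p <- 60
      bm <- random_beta_matrix(n_p, 5, seed = 100 + rep)
      ann <- ann_all_clear(bm)
      ann$cross_reactive <- runif(n_p) < 0.2
      ann$snp_overlap <- runif(n_p) < 0.2
      ann$autosomal <- runif(n_p) > 0.1
      detp <- matrix(runif(n_p * 5, 0, 0.008), n_p, 5,
                     dimnames = dimnames(bm$values))
      detp[runif(n_p * 5) < 0.03] <- 0.5  # sprinkle detection failures
      bm <- beta_matrix(bm$values, detection_p = detp)
      res <- filter_probes(bm, ann)

      # independent recount in the same stage order
      left <- ann$probe_id
      fails_detp <- ann$probe_id[apply(detp > 0.01, 1, any)]
      stages <- list(ann$probe_id[ann$cross_reactive], fails_detp,
                     ann$probe_id[ann$snp_overlap],
                     ann$probe_id[!ann$autosomal])
      counts <- integer(4)
      for (s in seq_along(stages)) {
        gone <- intersect(left, stages[[s]])
        counts[s] <- length(gone)
        left <- setdiff(left, gone)
      }
      expect_identical(res$report$n_removed, counts)
      expect_identical(probe_ids(res$beta), left)
    }
  })
})

test_that("filtering is idempotent", {
  bm <- random_beta_matrix(50, 4, seed = 12)
  ann <- ann_all_clear(bm)
  ann$cross_reactive <- rep(c(TRUE, FALSE), 25)
  once <- filter_probes(bm, ann)
  twice <- filter_probes(once$beta, ann)
  expect_identical(twice$beta$values, once$beta$values)
  expect_identical(twice$report$n_removed, rep(0L, 4))
})

test_that("the detp_fraction dialect relaxes the any-sample rule", {
  bm <- random_beta_matrix(10, 4, seed = 14)
  detp <- matrix(0.001, 10, 4, dimnames = dimnames(bm$values))
  detp[1, 1] <- 0.5          # fails in 25% of samples
  detp[2, 1:2] <- 0.5        # fails in 50%
  bm <- beta_matrix(bm$values, detection_p = detp)
  ann <- ann_all_clear(bm)
  any_rule <- filter_probes(bm, ann)
  expect_equal(any_rule$report$n_removed[2], 2L)
  frac_rule <- filter_probes(bm, ann, detp_fraction = 0.5)
  expect_equal(frac_rule$report$n_removed[2], 1L)
})

test_that("unannotated probes are an error naming the ids", {
  bm <- random_beta_matrix(5, 3, seed = 2)
  ann <- ann_all_clear(bm)[-2, ]
  expect_error(filter_probes(bm, ann), probe_ids(bm)[2])
})

test_that("platform restriction keeps the intersection in matrix order", {
  bm <- random_beta_matrix(20, 3, seed = 6)
  all_ids <- probe_ids(bm)
  expect_identical(restrict_to_platform(bm, all_ids)$values, bm$values)

  half <- all_ids[seq(1, 20, by = 2)]
  kept <- restrict_to_platform(bm, rev(half))  # order of set irrelevant
  expect_identical(probe_ids(kept), half)

  withr::with_seed(3, {
    for (rep in 1:5) {
      ss <- sample(c(all_ids, sprintf("cgX%03d", 1:10)), 12)
      expect_identical(probe_ids(restrict_to_platform(bm, ss)),
                       intersect(all_ids, ss))
    }
  })
  expect_error(restrict_to_platform(bm, "cg_not_there"), "no probes")
})

test_that("median imputation reproduces per-probe medians exactly", {
  m <- matrix(c(0.2, NA, 0.4, 0.6), 1, 4,
              dimnames = list("cg1", paste0("s", 1:4)))
  out <- impute_missing(beta_matrix(m))
  expect_equal(out$values["cg1", "s2"], 0.4)

  bm <- random_beta_matrix(50, 10, seed = 22, missing = 50)
  out <- impute_missing(bm)
  expect_false(anyNA(out$values))
  # untouched non-missing cells
  keep <- !is.na(bm$values)
  expect_identical(out$values[keep], bm$values[keep])
  # every imputed cell equals the independently computed probe median
  idx <- which(is.na(bm$values), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    expect_identical(out$values[idx[k, 1], idx[k, 2]],
                     stats::median(bm$values[idx[k, 1], ], na.rm = TRUE))
  }
})

test_that("fully missing probes need a fallback median", {
  m <- matrix(c(NA, NA, 0.5, 0.7), 2, 2, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  expect_error(impute_missing(beta_matrix(m)), "cg1")
  out <- impute_missing(beta_matrix(m), fallback_medians = c(cg1 = 0.3))
  expect_equal(unname(out$values["cg1", ]), c(0.3, 0.3))
})

test_that("imputation is the identity when nothing is missing", {
  bm <- random_beta_matrix(10, 4, seed = 30)
  expect_identical(impute_missing(bm)$values, bm$values)
})
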