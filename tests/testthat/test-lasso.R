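test_that("orthonormal design reproduces the closed-form soft threshold", {
  # 5 orthonormal predictors (in the 1/n inner product), centred y
  n <- 20
  base <- stats::contr.helmert(n)[, 1:5]           # orthogonal, zero-mean
  Xs <- sweep(base, 2, sqrt(colMeans(base^2)), "/")  # unit 1/n variance
  colnames(Xs) <- paste0("cg", 1:5)
  withr::with_seed(41, {
    y <- drop(Xs %*% c(3, -2, 1.5, 0.2, 0)) + rnorm(n, 0, 0.1)
  })
  b_ols <- drop(crossprod(Xs, y)) / n
  for (lam in c(0.05, 0.5, 1.5)) {
    oracle <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    fit <- fit_lasso(Xs, y, lam, standardize = FALSE, tol = 1e-14)
    got <- stats::setNames(rep(0, 5), colnames(Xs))
    got[names(fit$coefficients)] <- fit$coefficients
    expect_equal(unname(got), unname(oracle), tolerance = 1e-6)
    expect_equal(fit$intercept, mean(y), tolerance = 1e-8)
  }
})

test_that("objective matches an independent solver on a random problem", {
  withr::with_seed(43, {
    n <- 200; p <- 50
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("cg", seq_len(p))
    y <- drop(X[, 1:5] %*% rnorm(5, 0, 2)) + rnorm(n)
  })
  for (lam in c(0.02, 0.2)) {
    mine <- fit_lasso(X, y, lam, tol = 1e-13)
    ref <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, thresh = 1e-14,
                          standardize = TRUE)
    b_ref <- stats::setNames(as.numeric(ref$beta), rownames(ref$beta))
    b_ref <- b_ref[b_ref != 0]
    o_mine <- lasso_objective(X, y, mine$intercept, mine$coefficients, lam)
    o_ref <- lasso_objective(X, y, as.numeric(ref$a0), b_ref, lam)
    expect_lt(abs(o_mine - o_ref) / o_ref, 1e-6)
  }
})

test_that("penalties at or above lambda_max give the null model", {
  withr::with_seed(45, {
    X <- matrix(runif(50 * 30), 50)
    colnames(X) <- paste0("cg", 1:30)
    y <- rnorm(50, 280, 9)
  })
  lmax <- lambda_max(X, y)
  for (lam in c(lmax, lmax * 1.01, lmax * 10)) {
    fit <- fit_lasso(X, y, lam)
    expect_length(fit$coefficients, 0)
    expect_equal(fit$intercept, mean(y), tolerance = 1e-13)
  }
})

test_that("KKT conditions hold at the reported solution", {
  withr::with_seed(47, {
    X <- matrix(rnorm(100 * 40), 100)
    colnames(X) <- paste0("cg", 1:40)
    y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(100)
  })
  fit <- fit_lasso(X, y, 0.1, tol = 1e-13)
  expect_lt(fit$kkt / stats::sd(y), 1e-6)
})

test_that("cross-validation returns a coherent curve and seeded folds", {
  withr::with_seed(49, {
    X <- matrix(rnorm(120 * 60), 120)
    colnames(X) <- paste0("cg", 1:60)
    y <- drop(X[, 1:5] %*% rnorm(5, 0, 1.5)) + rnorm(120)
  })
  cfg <- train_config(n_folds = 5, seed = 3)
  cv <- cross_validate_lambda(X, y, cfg)
  expect_equal(nrow(cv$cv_curve), 100)
  expect_true(all(cv$cv_curve$cvm >= 0))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  cv2 <- cross_validate_lambda(X, y, cfg)
  expect_identical(cv$foldid, cv2$foldid)
  expect_identical(cv$lambda, cv2$lambda)
  expect_error(cross_validate_lambda(X, rep(280, 120), cfg), "constant")
})

test_that("pure-noise response selects a near-empty model", {
  withr::with_seed(11, {
    X <- matrix(rnorm(150 * 80), 150)
    colnames(X) <- paste0("cg", 1:80)
    y <- rnorm(150)
  })
  cv <- cross_validate_lambda(X, y, train_config(n_folds = 5, seed = 11))
  fit <- fit_lasso(X, y, cv$lambda)
  expect_lte(length(fit$coefficients), 2)
})

test_that("strong-signal cross-validation keeps the true support", {
  cfg <- sim_config(n_samples = 250, n_probes = 600, n_active = 30,
                    signal_fraction = 0.85, seed = 13)
  co <- simulate_cohort(cfg)
  X <- beta_design(co$beta)
  y <- as.numeric(co$truth$true_ga_days)
  cv <- cross_validate_lambda(X, y, train_config(n_folds = 5, seed = 13))
  fit <- fit_lasso(X, y, cv$lambda)
  hits <- sum(co$truth$active_probe_ids %in% names(fit$coefficients))
  expect_gte(hits, 27)
})
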