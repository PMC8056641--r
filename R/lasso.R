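#' Training configuration for a gestational age clock
#'
#' Defaults mirror common practice for methylation clocks: a pure Lasso
#' penalty (`alpha = 1`), tenfold cross-validation, an 80/20 train/test
#' split, internal standardisation of predictors, and a 100-point
#' log-spaced lambda grid from `lambda_max` (the smallest penalty giving the
#' null model) down to `0.001 * lambda_max`.
#'
#' @param alpha penalty mixing; only the Lasso (`1`) is supported.
#' @param n_folds number of cross-validation folds (`>= 2`).
#' @param lambda_grid optional decreasing positive penalty sequence;
#'   derived from the data when `NULL`.
#' @param lambda_rule `"min"` (penalty minimising mean CV error) or `"1se"`
#'   (largest penalty within one standard error of that minimum).
#' @param train_fraction fraction of samples assigned to training by
#'   [split_train_test()].
#' @param seed integer seed for fold assignment and splits.
#' @param standardize centre and scale predictors internally before
#'   penalisation (coefficients are always reported on the beta scale).
#' @param n_lambda,lambda_min_ratio grid shape when `lambda_grid` is `NULL`.
#' @return A `train_config` list.
#' @export
train_config <- function(alpha = 1, n_folds = 10, lambda_grid = NULL,
                         lambda_rule = c("min", "1se"), train_fraction = 0.8,
                         seed = 1L, standardize = TRUE, n_lambda = 100,
                         lambda_min_ratio = 0.001) {
  lambda_rule <- match.arg(lambda_rule)
  if (alpha != 1) stop("only the Lasso (alpha = 1) is supported", call. = FALSE)
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || any(diff(lambda_grid) >= 0)) {
      stop("lambda_grid must be positive and strictly decreasing", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_grid = lambda_grid, lambda_rule = lambda_rule,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 standardize = standardize, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "train_config")
}

#' Smallest penalty yielding the all-zero Lasso model
#'
#' `lambda_max = max_j |<x_j, y - mean(y)>| / n` over (standardised)
#' predictor columns; at or above it the Lasso solution is the null model
#' with intercept `mean(y)`.
#'
#' @param X samples x predictors numeric matrix.
#' @param y numeric response.
#' @param standardize scale columns to unit 1/n-variance first.
#' @return A single number.
#' @export
lambda_max <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)", call. = FALSE)
  .lambda_max_cpp(X, as.numeric(y), standardize)
}

default_lambda_grid <- function(X, y, cfg) {
  lmax <- lambda_max(X, y, standardize = cfg$standardize)
  if (lmax <= 0) stop("response has no covariance with any predictor",
                      call. = FALSE)
  exp(seq(log(lmax), log(lmax * cfg$lambda_min_ratio),
          length.out = cfg$n_lambda))
}

#' Fit the Lasso at fixed penalties by coordinate descent
#'
#' Minimises `(1/2n) * sum((y - b0 - X b)^2) + lambda * sum(|b|)` by cyclic
#' coordinate descent with an active-set strategy and warm starts along a
#' decreasing `lambda` sequence. Predictors are centred (and scaled when
#' `standardize`) internally; returned coefficients are on the original
#' scale with zero entries dropped.
#'
#' @param X samples x predictors numeric matrix with column names.
#' @param y numeric response (gestational age, days).
#' @param lambda a single penalty or a decreasing sequence.
#' @param standardize scale predictors to unit 1/n-variance internally.
#' @param tol convergence tolerance: a sweep converges when the largest
#'   coordinate update falls below `tol * sd(y)`.
#' @param max_sweeps cap on coordinate sweeps per penalty.
#' @return For a single `lambda`, a list with `intercept`, `coefficients`
#'   (named, non-zero), `lambda`, `kkt` (max KKT violation) and `sweeps`.
#'   For a sequence, a `lasso_path` list with the per-lambda intercepts and
#'   a dense coefficient matrix.
#' @export
fit_lasso <- function(X, y, lambda, standardize = TRUE, tol = 1e-7,
                      max_sweeps = 100000L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y)) stop("X and y must be numeric",
                                             call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)", call. = FALSE)
  if (nrow(X) < 2) stop("need at least two samples", call. = FALSE)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y; impute missing betas first",
         call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be nonnegative", call. = FALSE)
  single <- length(lambda) == 1
  lam <- as.numeric(lambda)
  if (!single && any(diff(lam) >= 0)) {
    stop("lambda sequence must be strictly decreasing", call. = FALSE)
  }
  fit <- .lasso_path_cpp(X, as.numeric(y), lam, standardize, tol,
                         as.integer(max_sweeps))
  rownames(fit$beta) <- colnames(X)
  if (single) {
    b <- fit$beta[, 1]
    list(intercept = fit$a0[1], coefficients = b[b != 0], lambda = lam,
         kkt = fit$kkt[1], sweeps = fit$sweeps[1])
  } else {
    structure(list(a0 = fit$a0, beta = fit$beta, lambda = lam,
                   kkt = fit$kkt, sweeps = fit$sweeps),
              class = "lasso_path")
  }
}

#' Select the Lasso penalty by K-fold cross-validation
#'
#' Samples are partitioned into `cfg$n_folds` near-equal folds by a seeded
#' random permutation; for every penalty on the grid the mean squared
#' held-out prediction error is accumulated across folds. The selected
#' penalty is the error minimiser (`lambda_rule = "min"`) or the largest
#' penalty within one standard error of it (`"1se"`).
#'
#' @param X samples x predictors matrix (no missing values).
#' @param y numeric response.
#' @param cfg a [train_config()].
#' @return A `ga_cv` list: `lambda` (selected), `lambda_min`, `lambda_1se`,
#'   `cv_curve` (tibble: `lambda`, `cvm`, `cvsd`, `nonzero`), `foldid`.
#' @export
cross_validate_lambda <- function(X, y, cfg = train_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < cfg$n_folds) stop("fewer samples than folds", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("constant response: nothing to cross-validate", call. = FALSE)
  }
  grid <- cfg$lambda_grid %||% default_lambda_grid(X, y, cfg)
  foldid <- with_seed(derive_seed(cfg$seed, 2L),
                      sample(rep(seq_len(cfg$n_folds), length.out = n)))
  nlam <- length(grid)
  fold_mse <- matrix(NA_real_, cfg$n_folds, nlam)
  sse <- numeric(nlam)
  for (k in seq_len(cfg$n_folds)) {
    hold <- foldid == k
    fit <- fit_lasso(X[!hold, , drop = FALSE], y[!hold], grid,
                     standardize = cfg$standardize)
    pred <- sweep(X[hold, , drop = FALSE] %*% fit$beta, 2, fit$a0, "+")
    err <- (pred - y[hold])^2
    fold_mse[k, ] <- colMeans(err)
    sse <- sse + colSums(err)
  }
  cvm <- sse / n
  cvsd <- apply(fold_mse, 2, stats::sd) / sqrt(cfg$n_folds)
  i_min <- which.min(cvm)
  lambda_min <- grid[i_min]
  ok_1se <- cvm <= cvm[i_min] + cvsd[i_min]
  lambda_1se <- grid[which(ok_1se)[1]]  # grid is decreasing: first = largest

  full <- fit_lasso(X, y, grid, standardize = cfg$standardize)
  curve <- tibble::tibble(lambda = grid, cvm = cvm, cvsd = cvsd,
                          nonzero = colSums(full$beta != 0))
  structure(list(
    lambda = if (cfg$lambda_rule == "min") lambda_min else lambda_1se,
    lambda_min = lambda_min, lambda_1se = lambda_1se,
    lambda_rule = cfg$lambda_rule, cv_curve = curve, foldid = foldid
  ), class = "ga_cv")
}

#' @export
print.ga_cv <- function(x, ...) {
  cat(sprintf(
    "<ga_cv> %d penalties; lambda_min = %.4g, lambda_1se = %.4g (rule: %s)\n",
    nrow(x$cv_curve), x$lambda_min, x$lambda_1se, x$lambda_rule))
  invisible(x)
}

#' @export
tidy.ga_cv <- function(x, ...) x$cv_curve

`%||%` <- function(a, b) if (is.null(a)) b else a
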