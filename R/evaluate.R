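#' Precision and accuracy of a gestational age prediction
#'
#' Regresses predicted GA on clinically estimated GA with
#' [mm_robust_fit()] and reports, in days where applicable:
#'
#' * `r2` — proportion of variance explained by the robust fit. With the
#'   default `r2_method = "weighted"` it uses the fit's final bisquare
#'   weights `w`, residuals `r`, and the weighted mean of the response:
#'   `1 - sum(w r^2) / sum(w (pred - weighted.mean(pred, w))^2)`. The
#'   `"cor"` method is the plain squared Pearson correlation instead.
#' * `se` — the robust residual scale of the MM fit.
#' * `mad_days` — the median absolute deviation between observed and
#'   predicted GA, `median(|pred - obs|)`, with no consistency factor.
#'
#' The regression direction follows the convention of regressing the DNAm
#' prediction on the clinical estimate; `direction = "clinical_on_dnam"`
#' swaps it (MAD is unaffected).
#'
#' @param obs clinical (ultrasound) gestational ages, days.
#' @param pred DNAm-predicted gestational ages, days; a `predict_ga()`
#'   tibble is also accepted (its `ga_dnam_days` column is used, aligned on
#'   nothing — supply vectors already aligned on the same individuals).
#' @param r2_method `"weighted"` (robust-weighted) or `"cor"`.
#' @param direction which variable is the regression response.
#' @param seed seed for the MM subsampling stage.
#' @return A `ga_eval` object with fields `r2`, `se`, `mad_days`, `n` and
#'   the underlying `mm_fit`.
#' @export
compute_metrics <- function(obs, pred, r2_method = c("weighted", "cor"),
                            direction = c("dnam_on_clinical",
                                          "clinical_on_dnam"),
                            seed = 42L) {
  r2_method <- match.arg(r2_method)
  direction <- match.arg(direction)
  if (is.data.frame(pred)) pred <- pred$ga_dnam_days
  obs <- as.numeric(obs)
  pred <- as.numeric(pred)
  if (length(obs) != length(pred)) {
    stop("obs and pred must be aligned vectors of equal length", call. = FALSE)
  }
  if (length(obs) < 5) stop("need at least five observations", call. = FALSE)
  if (direction == "dnam_on_clinical") {
    fit <- mm_robust_fit(obs, pred, seed = seed)
    resp <- pred
  } else {
    fit <- mm_robust_fit(pred, obs, seed = seed)
    resp <- obs
  }
  w <- fit$weights
  r <- fit$residuals
  r2 <- if (r2_method == "weighted") {
    mw <- stats::weighted.mean(resp, w)
    tot <- sum(w * (resp - mw)^2)
    if (tot <= 0) 1 else 1 - sum(w * r^2) / tot
  } else {
    stats::cor(obs, pred)^2
  }
  structure(list(r2 = r2, se = fit$scale,
                 mad_days = stats::median(abs(pred - obs)),
                 n = length(obs), fit = fit, obs = obs, pred = pred),
            class = "ga_eval")
}

#' @export
print.ga_eval <- function(x, ...) {
  cat(sprintf("<ga_eval> n = %d: R2 = %.3f, SE = %.2f days, MAD = %.2f days\n",
              x$n, x$r2, x$se, x$mad_days))
  invisible(x)
}

#' @export
tidy.ga_eval <- function(x, ...) {
  tibble::tibble(metric = c("r2", "se", "mad_days"),
                 value = c(x$r2, x$se, x$mad_days))
}

#' @export
glance.ga_eval <- function(x, ...) {
  tibble::tibble(r2 = x$r2, se = x$se, mad_days = x$mad_days, n = x$n,
                 converged = x$fit$converged)
}

#' Paired-bootstrap comparison of two prediction sets
#'
#' Compares two clocks (or GA estimation methods) on the same individuals.
#' Each bootstrap replicate draws individuals with replacement once and
#' evaluates [compute_metrics()] for *both* prediction sets on that same
#' resample — the paired design that accounts for the shared dataset — with
#' no model refitting. Differences are `metric_a - metric_b`; 95%
#' confidence intervals are standard percentile intervals of the replicate
#' differences, and a difference is flagged significant when its interval
#' excludes 0.
#'
#' Replicates where the robust fit fails (e.g. a degenerate resample) are
#' dropped and counted; more than 5% dropped raises a warning recorded in
#' the result.
#'
#' @param obs clinical gestational ages, days.
#' @param pred_a,pred_b the two prediction sets, aligned on the same
#'   individuals as `obs`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param ci_level confidence level for the percentile intervals.
#' @param ... passed on to [compute_metrics()].
#' @return A `ga_boot` object: point differences `delta` (full-sample),
#'   percentile intervals `ci`, `significant` flags, the replicate
#'   differences tibble, `n_boot`, `n_dropped`, `seed`.
#' @export
bootstrap_compare <- function(obs, pred_a, pred_b, n_boot = 1000L, seed = 1L,
                              ci_level = 0.95, ...) {
  if (is.data.frame(pred_a)) pred_a <- pred_a$ga_dnam_days
  if (is.data.frame(pred_b)) pred_b <- pred_b$ga_dnam_days
  obs <- as.numeric(obs)
  n <- length(obs)
  if (length(pred_a) != n || length(pred_b) != n) {
    stop("obs, pred_a, pred_b must be aligned on the same individuals",
         call. = FALSE)
  }
  full_a <- compute_metrics(obs, pred_a, ...)
  full_b <- compute_metrics(obs, pred_b, ...)
  delta <- c(r2 = full_a$r2 - full_b$r2,
             se = full_a$se - full_b$se,
             mad_days = full_a$mad_days - full_b$mad_days)

  draws <- with_seed(derive_seed(seed, 3L),
                     matrix(sample.int(n, n * n_boot, replace = TRUE),
                            nrow = n))
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("r2", "se", "mad_days")))
  for (b in seq_len(n_boot)) {
    idx <- draws[, b]
    res <- tryCatch({
      ma <- compute_metrics(obs[idx], pred_a[idx], seed = derive_seed(seed, b),
                            ...)
      mb <- compute_metrics(obs[idx], pred_b[idx], seed = derive_seed(seed, b),
                            ...)
      c(ma$r2 - mb$r2, ma$se - mb$se, ma$mad_days - mb$mad_days)
    }, error = function(e) NULL)
    if (!is.null(res)) reps[b, ] <- res
  }
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  warn <- NULL
  if (n_dropped > 0.05 * n_boot) {
    warn <- sprintf("%d of %d bootstrap replicates dropped (robust fit failed)",
                    n_dropped, n_boot)
    warning(warn, call. = FALSE)
  }
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = probs)
  significant <- ci[1, ] > 0 | ci[2, ] < 0

  structure(list(delta = delta, ci = ci, significant = significant,
                 replicates = tibble::as_tibble(reps[ok, , drop = FALSE]),
                 n_boot = as.integer(n_boot), n_dropped = n_dropped,
                 ci_level = ci_level, seed = as.integer(seed),
                 warning = warn, eval_a = full_a, eval_b = full_b),
            class = "ga_boot")
}

#' @export
print.ga_boot <- function(x, ...) {
  cat(sprintf("<ga_boot> %d replicates (%d dropped), %.0f%% percentile CIs\n",
              x$n_boot, x$n_dropped, 100 * x$ci_level))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.ga_boot <- function(x, ...) {
  tibble::tibble(metric = names(x$delta),
                 delta = unname(x$delta),
                 ci_lower = x$ci[1, names(x$delta)],
                 ci_upper = x$ci[2, names(x$delta)],
                 significant = unname(x$significant[names(x$delta)]))
}

#' @export
glance.ga_boot <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_dropped = x$n_dropped,
                 ci_level = x$ci_level, seed = x$seed)
}
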