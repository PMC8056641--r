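#' Split samples into training and test sets
#'
#' A seeded random permutation assigns `round(train_fraction * n)` samples
#' to training and the rest to test; the two sets are disjoint and
#' exhaustive.
#'
#' @param samples character vector of sample ids (or a sample sheet, whose
#'   `sample_id` column is used).
#' @param train_fraction fraction assigned to training, strictly in (0, 1).
#' @param seed integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
split_train_test <- function(samples, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(samples)) samples <- samples$sample_id
  samples <- as.character(samples)
  n <- length(samples)
  if (n < 2) stop("need at least two samples to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = samples[sort(idx)], test = samples[sort(setdiff(seq_len(n), idx))])
}

#' Train a gestational age clock
#'
#' Composes the training pipeline on one set of samples: median imputation
#' of missing betas, cross-validated penalty selection, and a final Lasso
#' fit at the selected penalty on all supplied samples. The gestational age
#' regressed on is either the clinical ultrasound estimate
#' (`ga_source = "ultrasound"`) or the embryo-transfer-date estimate
#' (`"etd"`, ART samples only; run [annotate_etd()] first).
#'
#' @param bm a [beta_matrix()] holding the training samples.
#' @param sheet sample sheet covering the samples of `bm`.
#' @param cfg a [train_config()].
#' @param ga_source `"ultrasound"` or `"etd"`.
#' @return A [ga_clock()] with training medians and metadata; the
#'   cross-validation object is attached as attribute `"cv"`.
#' @export
train_clock <- function(bm, sheet, cfg = train_config(),
                        ga_source = c("ultrasound", "etd")) {
  ga_source <- match.arg(ga_source)
  stopifnot(inherits(bm, "beta_matrix"), inherits(cfg, "train_config"))
  sheet <- as_sample_sheet(sheet)
  ids <- sample_ids(bm)
  missing_rows <- setdiff(ids, sheet$sample_id)
  if (length(missing_rows) > 0) {
    stop("samples absent from sample sheet: ",
         paste(utils::head(missing_rows, 10), collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[match(ids, sheet$sample_id), ]
  ga <- switch(ga_source,
               ultrasound = sheet$ga_ultrasound_days,
               etd = sheet$ga_etd_days)
  if (ga_source == "etd" && any(!sheet$art)) {
    stop("ETD-trained clocks use ART samples only; non-ART samples: ",
         paste(utils::head(sheet$sample_id[!sheet$art], 10), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ga))) {
    stop("missing ", ga_source, " GA for samples: ",
         paste(utils::head(sheet$sample_id[is.na(ga)], 10), collapse = ", "),
         call. = FALSE)
  }

  bm <- impute_missing(bm)
  X <- beta_design(bm)
  cv <- cross_validate_lambda(X, as.numeric(ga), cfg)
  fit <- fit_lasso(X, as.numeric(ga), cv$lambda, standardize = cfg$standardize)

  kept <- names(fit$coefficients)
  medians <- apply(bm$values[kept, , drop = FALSE], 1, stats::median)
  clock <- ga_clock(intercept = fit$intercept,
                    coefficients = fit$coefficients,
                    training_medians = medians,
                    alpha = cfg$alpha, lambda = cv$lambda,
                    n_folds = cfg$n_folds, seed = cfg$seed)
  attr(clock, "cv") <- cv
  clock
}

#' Predict gestational age with a clock
#'
#' For each sample the prediction is the clock intercept plus the linear
#' combination of beta values and coefficients over the clock CpGs. A clock
#' probe missing for some samples is imputed from its median across the
#' supplied dataset; a probe absent from the dataset altogether falls back
#' to the clock's training median, and is excluded (with a count) when no
#' training median is recorded — the treatment published clocks receive on
#' arrays that lack some of their CpGs.
#'
#' @param bm a [beta_matrix()].
#' @param clock a [ga_clock()].
#' @return A tibble with columns `sample_id` and `ga_dnam_days`, with
#'   attributes `absent_probes` (clock probes not in `bm`) and
#'   `excluded_probes` (absent with no training median, dropped from the
#'   linear combination).
#' @examples
#' clock <- ga_clock(280, c(cg1 = 10, cg2 = -5),
#'                   training_medians = c(cg1 = 0.5, cg2 = 0.2))
#' m <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' predict_ga(beta_matrix(m), clock)  # 280 + 5 - 1 = 284 days
#' @export
predict_ga <- function(bm, clock) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(clock, "ga_clock"))
  coefs <- clock$coefficients
  sids <- sample_ids(bm)
  if (length(coefs) == 0) {
    out <- tibble::tibble(sample_id = sids,
                          ga_dnam_days = rep(clock$intercept, length(sids)))
    attr(out, "absent_probes") <- character()
    attr(out, "excluded_probes") <- character()
    return(out)
  }
  present <- intersect(names(coefs), probe_ids(bm))
  absent <- setdiff(names(coefs), present)
  if (length(present) == 0) {
    stop("none of the clock's ", length(coefs),
         " CpGs are present in the beta matrix", call. = FALSE)
  }

  v <- bm$values[present, , drop = FALSE]
  if (anyNA(v)) {
    med <- apply(v, 1, stats::median, na.rm = TRUE)
    none_obs <- is.na(med) | is.nan(med)
    if (any(none_obs)) {
      ids <- present[none_obs]
      fb <- clock$training_medians
      if (is.null(fb) || !all(ids %in% names(fb))) {
        stop("clock probes with no observed values and no training median: ",
             paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
      }
      med[none_obs] <- fb[ids]
    }
    idx <- which(is.na(v), arr.ind = TRUE)
    v[is.na(v)] <- med[idx[, 1]]
  }

  pred <- clock$intercept + as.numeric(crossprod(v, coefs[present]))

  excluded <- character()
  if (length(absent) > 0) {
    fb <- clock$training_medians
    have_med <- if (is.null(fb)) rep(FALSE, length(absent)) else
      absent %in% names(fb)
    if (any(have_med)) {
      imp <- absent[have_med]
      pred <- pred + sum(coefs[imp] * fb[imp])
    }
    excluded <- absent[!have_med]
  }

  out <- tibble::tibble(sample_id = sids, ga_dnam_days = pred)
  attr(out, "absent_probes") <- absent
  attr(out, "excluded_probes") <- excluded
  out
}
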