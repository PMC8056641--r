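#' Construct a gestational age clock
#'
#' A `ga_clock` is a sparse linear predictor of gestational age (days) from
#' beta values: an intercept plus one coefficient (days per unit beta) for
#' each selected CpG. Training metadata (penalty mixing `alpha`, penalty
#' strength `lambda`, number of CV folds, seed) and the training-set beta
#' medians of the selected probes (the imputation fallback used when a probe
#' is unavailable at prediction time) travel with the model.
#'
#' @param intercept numeric, days.
#' @param coefficients named numeric vector, probe id -> coefficient; zero
#'   entries are dropped.
#' @param training_medians named numeric vector of training beta medians for
#'   (at least) every clock probe; may be `NULL` for externally supplied
#'   clocks without recorded medians.
#' @param alpha,lambda,n_folds,seed training metadata (optional).
#' @return An object of class `ga_clock`.
#' @export
ga_clock <- function(intercept, coefficients, training_medians = NULL,
                     alpha = NA_real_, lambda = NA_real_,
                     n_folds = NA_integer_, seed = NA_integer_) {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    stop("`intercept` must be a single finite number", call. = FALSE)
  }
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    stop("`coefficients` must be named by probe id", call. = FALSE)
  }
  if (anyDuplicated(names(coefficients))) {
    stop("duplicate probe ids in coefficients", call. = FALSE)
  }
  if (!is.null(training_medians)) {
    missing_med <- setdiff(names(coefficients), names(training_medians))
    if (length(missing_med) > 0) {
      stop("no training median for clock probes: ",
           paste(utils::head(missing_med, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 training_medians = training_medians, alpha = alpha,
                 lambda = lambda, n_folds = n_folds, seed = seed),
            class = "ga_clock")
}

#' @export
print.ga_clock <- function(x, ...) {
  cat(sprintf("<ga_clock> intercept %.3f days, %d CpGs", x$intercept,
              length(x$coefficients)))
  if (is.finite(x$lambda)) cat(sprintf(" (alpha = %g, lambda = %.4g)",
                                       x$alpha, x$lambda))
  cat("\n")
  invisible(x)
}

#' Tidy and summarise a clock
#'
#' `tidy()` returns one row per model term (Horvath-style, with an
#' `(Intercept)` row); `glance()` returns a one-row model summary.
#'
#' @param x a [ga_clock()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ga_clock <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    coefficient = c(x$intercept, unname(x$coefficients)),
    training_median = c(NA_real_, if (is.null(x$training_medians))
      rep(NA_real_, length(x$coefficients)) else
        unname(x$training_medians[names(x$coefficients)]))
  )
}

#' @rdname tidy.ga_clock
#' @export
glance.ga_clock <- function(x, ...) {
  tibble::tibble(n_cpgs = length(x$coefficients), intercept = x$intercept,
                 alpha = x$alpha, lambda = x$lambda, n_folds = x$n_folds,
                 seed = x$seed)
}

#' Read / write clock coefficient files
#'
#' The CSV interchange format used by published clocks: columns `term` and
#' `coefficient`, the intercept carried on a `term == "(Intercept)"` row, one
#' row per selected CpG otherwise. An optional `training_median` column
#' carries the training beta medians. Zero-coefficient rows are dropped on
#' read.
#'
#' @param path CSV file path.
#' @return `read_clock_file()` returns a [ga_clock()].
#' @export
read_clock_file <- function(path) {
  df <- readr::read_csv(path, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("term", "coefficient") %in% names(df))) {
    stop("clock file needs columns `term` and `coefficient`", call. = FALSE)
  }
  raw <- df$coefficient
  df$coefficient <- suppressWarnings(as.numeric(raw))
  if (any(is.na(df$coefficient))) {
    bad <- raw[is.na(df$coefficient)]
    stop("non-numeric coefficient in clock file: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if ("training_median" %in% names(df)) {
    df$training_median <- suppressWarnings(as.numeric(df$training_median))
  }
  is_int <- df$term == "(Intercept)"
  if (sum(is_int) != 1) {
    stop("clock file must contain exactly one `(Intercept)` row", call. = FALSE)
  }
  coefs <- stats::setNames(df$coefficient[!is_int], df$term[!is_int])
  medians <- NULL
  if ("training_median" %in% names(df)) {
    medians <- stats::setNames(df$training_median[!is_int], df$term[!is_int])
    medians <- medians[!is.na(medians)]
    if (length(medians) == 0) medians <- NULL
  }
  ga_clock(intercept = df$coefficient[is_int], coefficients = coefs,
           training_medians = medians)
}

#' @rdname read_clock_file
#' @param clock a [ga_clock()].
#' @export
write_clock_file <- function(clock, path) {
  readr::write_csv(fmt_doubles(tidy(clock)), path, na = "NA", progress = FALSE)
  invisible(path)
}
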