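#' Gestational age acceleration
#'
#' GAA is the discrepancy between epigenetic and clinical gestational age:
#' the residuals from an ordinary least-squares regression (with intercept)
#' of DNAm-predicted GA on the clinical ultrasound estimate. Positive GAA
#' means a newborn looks epigenetically "older" than its clinical GA.
#'
#' @param pred DNAm-predicted gestational ages, days (a [predict_ga()]
#'   tibble is accepted).
#' @param clinical clinical gestational ages, days, aligned with `pred`.
#' @return Numeric residual vector in days (named like `pred` if named);
#'   residuals sum to zero and are orthogonal to `clinical`.
#' @export
compute_gaa <- function(pred, clinical) {
  nms <- NULL
  if (is.data.frame(pred)) {
    nms <- pred$sample_id
    pred <- pred$ga_dnam_days
  } else {
    nms <- names(pred)
  }
  pred <- as.numeric(pred)
  clinical <- as.numeric(clinical)
  if (length(pred) != length(clinical)) {
    stop("pred and clinical must be aligned vectors", call. = FALSE)
  }
  if (length(pred) < 3) stop("need at least three observations", call. = FALSE)
  if (anyNA(pred) || anyNA(clinical)) {
    stop("missing values in pred or clinical", call. = FALSE)
  }
  if (stats::var(clinical) == 0) {
    stop("clinical GA is constant; residuals undefined", call. = FALSE)
  }
  res <- stats::lm.fit(cbind(1, clinical), pred)$residuals
  stats::setNames(as.numeric(res), nms)
}

#' Test gestational age acceleration against a binary group
#'
#' Logistic regression of group membership (ART vs non-ART, or an ART
#' subgroup contrast such as ICSI vs IVF or frozen vs fresh) on GAA, with a
#' Wald test of the GAA coefficient. Perfect separation is flagged and the
#' p-value reported as not estimable rather than trusted.
#'
#' @param gaa GAA residuals from [compute_gaa()], days.
#' @param group logical vector (or two-level factor; the second level is
#'   the event) aligned with `gaa`.
#' @return A `gaa_test` object: `logit_coef` (log-odds per day of GAA),
#'   `p_value`, `n_per_group`, `separation` flag, the fitted `glm`, and the
#'   data.
#' @export
test_gaa_association <- function(gaa, group) {
  gaa <- as.numeric(gaa)
  if (is.factor(group) || is.character(group)) {
    lev <- unique(as.character(group))
    if (length(lev) > 2) stop("group must be binary", call. = FALSE)
    group <- as.character(group) == sort(lev)[length(lev)]
  }
  group <- as.logical(group)
  if (length(gaa) != length(group)) {
    stop("gaa and group must be aligned", call. = FALSE)
  }
  if (anyNA(gaa) || anyNA(group)) stop("missing values", call. = FALSE)
  if (length(gaa) < 20) stop("need at least 20 observations", call. = FALSE)
  if (length(unique(group)) < 2) {
    stop("both groups must be present", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(group ~ gaa, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  logit_coef <- co["gaa", "Estimate"]
  p <- co["gaa", "Pr(>|z|)"]
  if (separation || abs(logit_coef) > 1e3) {
    separation <- TRUE
    p <- NA_real_
  }
  structure(list(logit_coef = logit_coef, p_value = p,
                 n_per_group = c(`FALSE` = sum(!group), `TRUE` = sum(group)),
                 separation = separation, glm = fit, gaa = gaa,
                 group = group),
            class = "gaa_test")
}

#' @export
print.gaa_test <- function(x, ...) {
  cat(sprintf(
    "<gaa_test> log-odds per day of GAA = %.4f, p = %s (n = %d vs %d)%s\n",
    x$logit_coef,
    if (is.na(x$p_value)) "not estimable" else format.pval(x$p_value, digits = 3),
    x$n_per_group[1], x$n_per_group[2],
    if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

#' @export
tidy.gaa_test <- function(x, ...) {
  tibble::tibble(term = "gaa", estimate = x$logit_coef,
                 p_value = x$p_value, separation = x$separation)
}

#' @export
glance.gaa_test <- function(x, ...) {
  tibble::tibble(logit_coef = x$logit_coef, p_value = x$p_value,
                 n_group_false = unname(x$n_per_group[1]),
                 n_group_true = unname(x$n_per_group[2]),
                 separation = x$separation)
}
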