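#' Plot a prediction evaluation
#'
#' Scatter of DNAm-predicted against clinical gestational age with the
#' identity line (red) and the MM-type robust regression line (black), the
#' standard display for clock validation.
#'
#' @param object a `ga_eval` from [compute_metrics()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ga_eval <- function(object, ...) {
  df <- tibble::tibble(clinical = object$obs, dnam = object$pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clinical, y = .data$dnam)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = object$fit$slope,
                         intercept = object$fit$intercept, colour = "black") +
    ggplot2::labs(
      x = "Ultrasound gestational age (days)",
      y = "DNAm gestational age (days)",
      subtitle = sprintf("R² = %.3f, SE = %.2f d, MAD = %.2f d (n = %d)",
                         object$r2, object$se, object$mad_days, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation curve
#'
#' Mean squared cross-validated prediction error against the penalty, with
#' one-standard-error bars and the selected penalties marked.
#'
#' @param object a `ga_cv` from [cross_validate_lambda()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ga_cv <- function(object, ...) {
  df <- object$cv_curve
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                        ymax = .data$cvm + .data$cvsd),
                           colour = "grey70", width = 0) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log(object$lambda_1se),
                        linetype = "dotted") +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "Mean CV squared error (days²)") +
    ggplot2::theme_minimal()
}

#' Plot a GAA association test
#'
#' Gestational age acceleration by group, the display used for ART
#' contrasts: jittered residuals with group medians.
#'
#' @param object a `gaa_test` from [test_gaa_association()].
#' @param group_labels length-2 labels for `FALSE`/`TRUE`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gaa_test <- function(object, group_labels = c("non-ART", "ART"),
                              ...) {
  df <- tibble::tibble(
    gaa = object$gaa,
    group = factor(ifelse(object$group, group_labels[2], group_labels[1]),
                   levels = group_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$gaa)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "red") +
    ggplot2::labs(x = NULL, y = "Gestational age acceleration (days)") +
    ggplot2::theme_minimal()
}

#' Scatter of GAA against clinical gestational age
#'
#' @param gaa residuals from [compute_gaa()].
#' @param clinical clinical gestational ages, days.
#' @param group optional logical grouping (e.g. ART status) for colour.
#' @param group_labels length-2 labels for `FALSE`/`TRUE`.
#' @return A ggplot.
#' @export
plot_gaa_scatter <- function(gaa, clinical, group = NULL,
                             group_labels = c("non-ART", "ART")) {
  df <- tibble::tibble(gaa = as.numeric(gaa), clinical = as.numeric(clinical))
  if (!is.null(group)) {
    df$group <- factor(ifelse(group, group_labels[2], group_labels[1]),
                       levels = group_labels)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$clinical, y = .data$gaa)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Ultrasound gestational age (days)",
                  y = "Gestational age acceleration (days)") +
    ggplot2::theme_minimal()
  if (is.null(group)) {
    p + ggplot2::geom_point(alpha = 0.5, size = 1)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                            alpha = 0.5, size = 1) +
      ggplot2::labs(colour = NULL)
  }
}
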