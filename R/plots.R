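#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the bias and
#' 95% limits of agreement drawn as horizontal lines.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements (mm)",
                  y = "Difference (mm)",
                  title = sprintf("Bias %.3f, 95%% LoA (%.3f, %.3f)",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Residual-correlation profile plot
#'
#' Dot plot of the residual Pearson correlations of a corrected series with
#' each physiological variable, with the ±0.20 biological-significance band
#' shaded. Points inside the band (or non-significant) indicate a successful
#' correction.
#'
#' @param object An [assess_efficacy()] report.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.efficacy_report <- function(object, ...) {
  df <- dplyr::filter(object$entries, .data$variable != "uncorrected")
  df$significant <- df$p < object$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$r,
                                   shape = .data$significant)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -object$r_threshold, ymax = object$r_threshold,
                      alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = sprintf("p < %.2f", object$alpha)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Residual Pearson r",
                  title = sprintf("%s / %s / %s: %s", object$population,
                                  object$param, object$method,
                                  if (object$success) "success" else "failure")) +
    ggplot2::theme_minimal()
}

#' Compare fitted corrected values across genders
#'
#' Box plot of corrected ratios by gender, a visual companion to
#' [gender_difference_test()].
#'
#' @param values Corrected series.
#' @param gender 0/1 codes aligned with `values`.
#'
#' @return A ggplot object.
#' @export
plot_gender_comparison <- function(values, gender) {
  df <- tibble::tibble(
    yc = values,
    gender = factor(gender, levels = c(0, 1), labels = c("men", "women"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gender, y = .data$yc)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Corrected ratio (Yc)") +
    ggplot2::theme_minimal()
}
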