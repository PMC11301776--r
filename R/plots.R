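# ggplot2 views of the result types.

#' Plot a calibration curve
#'
#' Replicate peak-area ratios against nominal concentration with the fitted
#' regression line.
#'
#' @param object A `calibration_fit`.
#' @param log_x Log-scale the concentration axis (useful for wide serial
#'   dilutions).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, log_x = FALSE, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$nominal,
                                                 y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "nominal concentration", y = "peak-area ratio (analyte / IS)",
      title = sprintf("%s: ratio = %.4g x + %.4g (R² = %.4f)",
                      object$analysis_id, object$slope, object$intercept,
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot recovery verdicts
#'
#' Mean back-calculated recovery per level with the acceptance band (dashed
#' lines at 100 ± tolerance, e.g. 85%/115%).
#'
#' @param verdicts An `acceptance_verdicts` tibble ([assess_calibrators()] or
#'   [assess_qc()]), or several row-bound together.
#' @return A ggplot.
#' @export
plot_recovery <- function(verdicts) {
  v <- as_tibble(verdicts)
  ggplot2::ggplot(v, ggplot2::aes(x = factor(.data$level),
                                  y = .data$mean_recovery_pct,
                                  colour = .data$pass)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 100, colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = c(100 - v$tolerance_pct, 100 + v$tolerance_pct),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "nominal level", y = "mean recovery (%)",
                  colour = "pass") +
    ggplot2::theme_minimal()
}

#' Plot a method comparison
#'
#' Per-sample mean concentrations under the two internal-standard methods,
#' with significance marks from the Wilcoxon comparison.
#'
#' @param comparison A `method_comparison` tibble ([compare_methods()]).
#' @param labels Length-2 method labels for the legend.
#' @return A ggplot.
#' @export
plot_method_comparison <- function(comparison,
                                   labels = c("method A", "method B")) {
  long <- as_tibble(comparison) |>
    tidyr::pivot_longer(c("mean_conc_a", "mean_conc_b"),
                        names_to = "method", values_to = "mean_conc") |>
    mutate(method = ifelse(.data$method == "mean_conc_a", labels[1],
                           labels[2]))
  marks <- as_tibble(comparison) |>
    mutate(mark = dplyr::case_when(.data$signif_01 ~ "**",
                                   .data$signif_05 ~ "*",
                                   TRUE ~ ""),
           y = pmax(.data$mean_conc_a, .data$mean_conc_b))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$mean_conc,
                                     colour = .data$method)) +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_text(data = marks,
                       ggplot2::aes(x = .data$sample_id, y = .data$y,
                                    label = .data$mark),
                       inherit.aes = FALSE, vjust = -0.8) +
    ggplot2::labs(x = "sample", y = "mean back-calculated concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
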