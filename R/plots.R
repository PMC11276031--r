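#' ENC-plot: per-gene ENC against GC3s with the mutation-only curve
#'
#' @param metrics Tibble from [metrics_table()] (columns `gc3s`, `enc`).
#' @return A ggplot object.
#' @export
plot_enc <- function(metrics) {
  curve_df <- tibble::tibble(gc3s = seq(0, 1, by = 0.005))
  curve_df$enc <- expected_enc(curve_df$gc3s)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_line(data = curve_df, colour = "black") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::theme_bw()
}

#' PR2 parity plot with 0.5 crosshairs
#'
#' @param pr2 Tibble from [pr2_point()] (columns `x`, `y`).
#' @return A ggplot object.
#' @export
plot_pr2 <- function(pr2) {
  ggplot2::ggplot(pr2, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)") +
    ggplot2::theme_bw()
}

#' Neutrality plot with the fitted regression line
#'
#' @param metrics Tibble with columns `gc3` and `gc12`.
#' @param fit Optional [neutrality_fit()] result (computed if missing).
#' @return A ggplot object.
#' @export
plot_neutrality <- function(metrics, fit = NULL) {
  if (is.null(fit)) fit <- neutrality_fit(metrics$gc12, metrics$gc3)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "black") +
    ggplot2::labs(x = "GC3", y = "GC12",
                  title = sprintf("slope = %.3f, r = %.3f",
                                  fit$slope, fit$pearson_r)) +
    ggplot2::theme_bw()
}

#' Correspondence analysis gene map (axes 1-2) coloured by GC class
#'
#' @param coa A [correspondence_analysis()] result with >= 2 axes.
#' @param gc Per-gene GC fractions matching the CoA rows (optional).
#' @return A ggplot object.
#' @export
plot_coa <- function(coa, gc = NULL) {
  stopifnot(ncol(coa$row_coords) >= 2)
  df <- tibble::tibble(axis1 = coa$row_coords[, 1], axis2 = coa$row_coords[, 2])
  lab <- function(i) sprintf("Axis %d (%.2f%%)", i, coa$percent_inertia[i])
  p <- if (is.null(gc)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue")
  } else {
    df$gc_class <- gc_class_labels(gc)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                     colour = .data$gc_class)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::scale_colour_manual(
        values = c(low = "blue", mid = "red", high = "green3"),
        name = "GC class")
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_bw()
}
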