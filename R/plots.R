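# ggplot2 visual summaries. The somatochart is drawn on plain X/Y axes
# (X = ecto - endo, Y = 2*meso - endo - ecto); the classic curved triangle
# outline is presentation furniture and is not reproduced.

#' Somatochart scatter plot
#'
#' Plots athletes on the somatochart plane, coloured by ranking and shaped
#' by sex, with group-mean somatoplots overlaid.
#'
#' @param data Data frame with `chart_x`, `chart_y` (from
#'   [add_somatotype()]) and the `sex`/`ranking` columns.
#' @param show_means Overlay group-mean somatoplots (default TRUE).
#' @return A ggplot object.
#' @export
plot_somatochart <- function(data, show_means = TRUE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$chart_x, y = .data$chart_y,
                                          colour = .data$ranking,
                                          shape = .data$sex)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "X (ectomorphy - endomorphy)",
                  y = "Y (2 x mesomorphy - endomorphy - ectomorphy)",
                  colour = "Ranking", shape = "Sex") +
    ggplot2::coord_equal(ratio = 1 / sqrt(3)) +
    ggplot2::theme_minimal()
  if (show_means) {
    means <- data |>
      dplyr::group_by(.data$sex, .data$ranking) |>
      dplyr::summarise(chart_x = mean(.data$chart_x),
                       chart_y = mean(.data$chart_y), .groups = "drop")
    p <- p + ggplot2::geom_point(data = means, size = 4, stroke = 1.5)
  }
  p
}

#' @method autoplot kin_comparison
#' @export
autoplot.kin_comparison <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$variable, y = .data$eta_sq_p,
                                    fill = .data$term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(0.01, 0.06, 0.14),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "partial eta-squared", fill = "Effect") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @method autoplot kin_correlation
#' @export
autoplot.kin_correlation <- function(object, ...) {
  tbl <- object$pairs
  both <- dplyr::bind_rows(
    tbl,
    dplyr::rename(tbl, var1 = "var2", var2 = "var1")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  plot_somatochart(object$data)
}
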