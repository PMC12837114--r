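# ggplot2 figure builders for the result types.

#' Accuracy bars with bootstrap CI whiskers
#'
#' One bar per row of a glanced selection report (or any tibble with
#' `accuracy`, `ci_low`, `ci_high` and a grouping column), with the
#' 6-target chance level (1/6) as a dashed line.
#'
#' @param reports A tibble of accuracy rows, e.g.
#'   `dplyr::bind_rows(lapply(reports, glance))`.
#' @param x Column (string) mapped to the x axis, default "condition".
#' @param fill Optional column mapped to fill, e.g. "decoder".
#' @param chance Chance-level accuracy drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(reports, x = "condition", fill = NULL,
                          chance = 1 / 6) {
  p <- ggplot2::ggplot(reports, ggplot2::aes(
    x = .data[[x]], y = .data$accuracy,
    fill = if (is.null(fill)) NULL else .data[[fill]]))
  p <- p + ggplot2::geom_col(position = ggplot2::position_dodge(0.9),
                             width = 0.8)
  p <- p + ggplot2::geom_errorbar(
    ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
    position = ggplot2::position_dodge(0.9), width = 0.25)
  p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "selection accuracy",
                  fill = fill %||% NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  plot_accuracy(glance(object), ...)
}

#' Cross-condition accuracy heatmap
#'
#' Train condition on the y axis, test condition on the x axis, tile fill
#' and label giving the pooled selection accuracy.
#'
#' @param mat A `cross_condition_matrix` from [cross_condition_eval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cross_condition_matrix
#' @export
autoplot.cross_condition_matrix <- function(mat, ...) {
  ggplot2::ggplot(mat, ggplot2::aes(x = .data$test_condition,
                                    y = .data$train_condition,
                                    fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$accuracy))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "test condition", y = "train condition",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Gaze density map over stimulus space
#'
#' 2-D histogram of valid fused gaze samples with target positions as
#' crosshairs, faceted by condition when present.
#'
#' @param fused Fused gaze trace, optionally with a `condition` column
#'   (join block metadata beforehand to get one).
#' @param positions Target positions from [target_positions()].
#' @param bins Number of 2-D histogram bins per axis.
#' @return A ggplot object.
#' @export
plot_gaze_density <- function(fused, positions, bins = 60) {
  valid <- dplyr::filter(fused, !is.na(.data$x), !is.na(.data$y))
  p <- ggplot2::ggplot(valid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_point(data = positions, shape = 3, size = 3,
                        color = "red") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "samples") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(valid)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Target-minus-nontarget contrast waveforms
#'
#' @param contrast Output of [erp_contrast()].
#' @param channels Channels to draw (default all).
#' @return A ggplot object.
#' @export
plot_erp_contrast <- function(contrast, channels = NULL) {
  if (!is.null(channels)) {
    contrast <- dplyr::filter(contrast, .data$channel %in% channels)
  }
  ggplot2::ggplot(contrast, ggplot2::aes(.data$t_s * 1000,
                                         .data$contrast_uv,
                                         color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (ms)", y = "target - nontarget (uV)") +
    ggplot2::theme_minimal()
}

#' Accuracy-by-repetitions curve with threshold line
#'
#' @param curve Output of [accuracy_by_repetitions()].
#' @param threshold Threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_accuracy_by_k <- function(curve, threshold = 0.8) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "averaged repetitions k", y = "selection accuracy") +
    ggplot2::theme_minimal()
}
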