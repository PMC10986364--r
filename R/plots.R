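#' Plot mRMR importance scores
#'
#' Bar chart of the rescaled importance of each variable in selection order.
#'
#' @param result A `selection_result`.
#' @return A ggplot object.
#' @export
plot_importance <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  df <- data.frame(variable = factor(result$ranked_names,
                                     levels = result$ranked_names),
                   importance = result$importance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "importance (rescaled mRMR score)") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param model A trained `p3d_model` (with `history`).
#' @return A ggplot object with loss and accuracy per epoch.
#' @export
plot_history <- function(model) {
  stopifnot(inherits(model, "p3d_model"), !is.null(model$history))
  h <- model$history
  df <- rbind(data.frame(epoch = h$epoch, value = h$loss, what = "loss"),
              data.frame(epoch = h$epoch, value = h$accuracy,
                         what = "accuracy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated metrics
#'
#' Mean and standard deviation of the four confusion-matrix metrics.
#'
#' @param report A `metrics_report`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  s <- report$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "cross-validated value") +
    ggplot2::theme_minimal()
}

#' Plot the electrode grid layout
#'
#' @param layout A `grid_layout`.
#' @return A ggplot object showing electrode placement on the 4x7 grid.
#' @export
plot_grid_layout <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  df <- data.frame(name = names(layout$mapping),
                   row = vapply(layout$mapping, `[`, 0, 1),
                   col = vapply(layout$mapping, `[`, 0, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   label = .data$name)) +
    ggplot2::geom_tile(fill = "white", colour = "grey50") +
    ggplot2::geom_text(size = 3) +
    ggplot2::scale_x_continuous(breaks = 1:7, limits = c(0.5, 7.5)) +
    ggplot2::scale_y_continuous(breaks = -(1:4), labels = 1:4,
                                limits = c(-4.5, -0.5)) +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}
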