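#' Plot a precision-recall curve
#'
#' @param object a `dotapet_pr_curve` (or a list of them, via
#'   [plot_pr_curves()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dotapet_pr_curve <- function(object, ...) {
  plot_pr_curves(list(object))
}

#' Overlay precision-recall curves for several pixel filters
#'
#' @param curves list of `dotapet_pr_curve` objects.
#' @return A ggplot object, one colored curve per pixel-area filter.
#' @export
plot_pr_curves <- function(curves) {
  df <- dplyr::bind_rows(lapply(curves, tidy))
  df$filter <- sprintf("%d px (AUC %.2f)", df$filter_px,
                       vapply(curves, function(x) x$auc,
                              numeric(1))[match(df$filter_px,
                                                vapply(curves, function(x)
                                                  x$area_filter_px,
                                                  integer(1)))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   color = .data$filter)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall (sensitivity)", y = "Precision (PPV)",
                  color = "Pixel filter") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training loss and validation metric per validation interval, with the
#' best-validation marker.
#'
#' @param object a `dotapet_train_history`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dotapet_train_history <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "val_metric"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", color = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one phantom slice with its masks
#'
#' @param study a `dotapet_study`.
#' @param slice slice index (default: the slice with the most lesion pixels,
#'   or the middle slice for normal studies).
#' @return A ggplot raster of activity with liver and lesion contours.
#' @export
plot_study_slice <- function(study, slice = NULL) {
  if (is.null(slice)) {
    per <- apply(study$lesions > 0, 1, sum)
    slice <- if (any(per > 0)) which.max(per) else ceiling(dim(study$pet)[1] / 2)
  }
  d <- dim(study$pet)
  df <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]))
  df$activity <- as.numeric(study$pet[slice, , ])
  df$liver <- as.numeric(study$liver[slice, , ])
  df$lesion <- as.numeric(study$lesions[slice, , ] > 0)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$activity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d", slice), x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (any(df$lesion > 0)) {
    gg <- gg + ggplot2::geom_contour(ggplot2::aes(z = .data$lesion),
                                     breaks = 0.5, color = "red",
                                     linewidth = 0.3)
  }
  gg + ggplot2::geom_contour(ggplot2::aes(z = .data$liver), breaks = 0.5,
                             color = "cyan", linewidth = 0.3)
}
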