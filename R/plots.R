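## ggplot2 visualizations for the main result types.

#' Plot a well's kinetic image
#'
#' Heatmap of the per-pixel maximum wavelength shift, with optional
#' centroid overlays.
#'
#' @param well a `well_video`, or a plain matrix.
#' @param centroids optional `(row, col)` matrix (e.g. local maxima).
#' @return a ggplot object.
#' @export
plot_kinetic_image <- function(well, centroids = NULL) {
  img <- if (inherits(well, "well_video")) kinetic_image(well) else well
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "max WS (pm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row")
  if (!is.null(centroids) && NROW(centroids) > 0) {
    cd <- tibble(row = centroids[, 1], col = centroids[, 2])
    p <- p + ggplot2::geom_point(data = cd,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE, color = "red", shape = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training history curves
#'
#' @param object an `nn_fit`.
#' @param ... unused.
#' @return a ggplot of loss and accuracy over epochs.
#' @export
autoplot.nn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  h$set <- ifelse(grepl("^train", h$metric), "train", "validation")
  h$what <- ifelse(grepl("loss$", h$metric), "loss", "accuracy")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), scales = "free_y") +
    ggplot2::labs(y = NULL, color = NULL)
}

#' Confusion-matrix heatmap
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot of the row-normalized confusion matrix.
#' @export
autoplot.classification_report <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "predicted", "fraction")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed()
}

#' Per-class precision-recall curves
#'
#' @param report a `classification_report`.
#' @return a ggplot object.
#' @export
plot_pr_curves <- function(report) {
  ggplot2::ggplot(report$pr_curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               color = .data$class)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1))
}

#' t-SNE embedding scatter plot
#'
#' @param embedding tibble from [embed_probabilities()].
#' @param labels optional per-row labels used for coloring.
#' @return a ggplot object.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne_1, y = .data$tsne_2))
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label), alpha = 0.7)
  }
}
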