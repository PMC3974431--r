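#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot aligned configurations and their consensus
#'
#' Aligned landmarks as a grey cloud with the consensus configuration
#' overlaid; the standard picture for judging superimposition quality.
#'
#' @param object a `gpa` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gpa <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble::tibble(landmark = seq_len(object$k),
                         x = object$consensus[, 1],
                         y = object$consensus[, 2])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "firebrick", size = 2) +
    ggplot2::geom_text(data = cons, ggplot2::aes(label = .data$landmark),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned configurations",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of the first two principal components
#' @param object a `shape_pca` object.
#' @param labels optional group label per row for colouring.
#' @param ... unused.
#' @export
autoplot.shape_pca <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(PC1 = object$scores[, 1],
                       PC2 = if (ncol(object$scores) > 1)
                         object$scores[, 2] else 0)
  pv <- object$percent_variance
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  } else {
    df$group <- labels
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     colour = .data$group))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", pv[1]),
      y = sprintf("PC2 (%.0f%%)", ifelse(length(pv) > 1, pv[2], 0))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#' @param object a `shape_confusion` object.
#' @param ... unused.
#' @export
autoplot.shape_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0,
                                                   .data$count, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(object$groups)) +
    ggplot2::labs(x = "predicted group", y = "true group",
                  title = "Leave-one-out cross-validation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Reference ordination with projected unknowns
#' @param object a `subspace_pca` object (see [restricted_shape_pca()]).
#' @param ... unused.
#' @export
autoplot.subspace_pca <- function(object, ...) {
  pv <- object$pca$percent_variance
  p <- ggplot2::ggplot(object$reference_scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", pv[1]),
      y = sprintf("PC2 (%.0f%%)", ifelse(length(pv) > 1, pv[2], 0))) +
    ggplot2::theme_minimal()
  if (!is.null(object$unknown_scores)) {
    p <- p + ggplot2::geom_point(data = object$unknown_scores,
                                 ggplot2::aes(colour = NULL),
                                 shape = 8, size = 3, colour = "black")
  }
  p
}
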