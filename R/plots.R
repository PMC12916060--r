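#' Heatmap of a view-by-object correlation matrix
#'
#' Perfect transform invariance appears as bright `n_views` x `n_views`
#' blocks along the diagonal (views of one object correlated with each
#' other) on a dark background (no correlation between objects).
#'
#' @param corr correlation matrix, rows object-major.
#' @param n_views views per object; when given, object boundaries are drawn.
#' @return a ggplot object.
#' @export
plot_correlation_matrix <- function(corr, n_views = NULL) {
  n <- nrow(corr)
  df <- data.frame(i = rep(seq_len(n), times = n),
                   j = rep(seq_len(n), each = n),
                   r = as.numeric(corr))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(min(0, min(corr)), 1),
                                 name = "r") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "transform (view within object)",
                  y = "transform (view within object)") +
    ggplot2::theme_minimal()
  if (!is.null(n_views) && n %% n_views == 0) {
    b <- seq(n_views, n - n_views, by = n_views) + 0.5
    p <- p + ggplot2::geom_vline(xintercept = b, colour = "grey40",
                                 linewidth = 0.2) +
      ggplot2::geom_hline(yintercept = b, colour = "grey40",
                          linewidth = 0.2)
  }
  p
}

#' Histogram of a Layer's synaptic weights
#'
#' @param network a `visnet_network`.
#' @param layer Layer index.
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_weight_distribution <- function(network, layer, bins = 60) {
  w <- as.numeric(network$layers[[layer]]$weights)
  mw <- network$layers[[layer]]$spec$max_weight
  p <- ggplot2::ggplot(data.frame(w = w), ggplot2::aes(x = .data$w)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = NA) +
    ggplot2::labs(x = sprintf("synaptic weight (Layer %d)", layer),
                  y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(mw))
    p <- p + ggplot2::geom_vline(xintercept = mw, colour = "red",
                                 linetype = "dashed")
  p
}

#' Selectivity versus object count from a capacity sweep
#'
#' @param sweep result of [capacity_sweep()].
#' @param criterion criterion line to draw.
#' @return a ggplot object.
#' @export
plot_capacity_sweep <- function(sweep, criterion = 0.6) {
  ggplot2::ggplot(sweep$table,
                  ggplot2::aes(x = .data$n_objects,
                               y = .data$selectivity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = criterion, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "objects trained", y = "object selectivity") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
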