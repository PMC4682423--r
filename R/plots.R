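#' Plot expression profiles
#'
#' Line plot of per-gene trajectories, optionally highlighting a subset
#' of genes (e.g. one planted module).
#'
#' @param object an [expression_matrix()].
#' @param genes optional character vector of genes to highlight.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.expression_matrix <- function(object, genes = NULL, ...) {
  df <- tidy(object)
  df$highlight <- if (is.null(genes)) TRUE else df$gene %in% genes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                   group = .data$gene,
                                   colour = .data$highlight)) +
    ggplot2::geom_line(alpha = 0.6, show.legend = !is.null(genes)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#D55E00"),
                                 name = "highlighted") +
    ggplot2::labs(x = "time point", y = "expression",
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' Plot a discretized matrix as an item heatmap
#'
#' @param object a `discretized_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.discretized_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$gene,
                                   fill = .data$item)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-3, 3)) +
    ggplot2::labs(x = "time point", y = NULL, fill = "item",
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution with its power-law fit
#'
#' Log-log scatter of `p(k)` against degree `k` with the fitted
#' least-squares line when the exponent is defined.
#'
#' @param object a `degree_stats` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.degree_stats <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "p(k)",
                  subtitle = if (is.na(object$exponent)) "exponent undefined"
                  else sprintf("fitted exponent %.2f", object$exponent)) +
    ggplot2::theme_minimal()
  if (!is.na(object$exponent)) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.4)
  }
  p
}

#' Plot integrative edge weights
#'
#' Tile plot of positive versus negative conservation weights, useful
#' for picking the `occ` threshold.
#'
#' @param object an `integrative_gin`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.integrative_gin <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$pos_weight, .data$neg_weight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_weight, y = .data$neg_weight,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "positive weight", y = "negative weight", fill = "edges") +
    ggplot2::theme_minimal()
}
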