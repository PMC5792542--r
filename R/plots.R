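# Diagnostic plots: group networks in space, and sweep scatter plots with a
# replicate-mean trend line.

#' Plot a simulated group in space
#'
#' Individuals at their positions, coloured by phenotype; edges drawn as
#' segments with opacity proportional to weight.
#'
#' @param group An `ipn_group`.
#' @param node_colour Individual column mapped to colour. Default `"z"`.
#' @return A ggplot.
#' @export
plot_group_network <- function(group, node_colour = "z") {
  stopifnot(inherits(group, "ipn_group"))
  ind <- group$individuals
  idx <- which(upper.tri(group$w) & group$w > 0, arr.ind = TRUE)
  edges <- tibble(
    x = ind$x[idx[, 1]], y = ind$y[idx[, 1]],
    xend = ind$x[idx[, 2]], yend = ind$y[idx[, 2]],
    weight = group$w[idx]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   alpha = .data$weight),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = ind,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = .data[[node_colour]]),
      size = 3
    ) +
    ggplot2::scale_alpha_continuous(range = c(0.05, 0.8), limits = c(0, 1)) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = node_colour,
                  alpha = "weight") +
    ggplot2::theme_minimal()
}

#' Scatter a sweep metric against density or assortativity
#'
#' One dot per simulated group, with the replicate-mean trend over the grid
#' as a line: the standard view of how a group statistic responds to emergent
#' network structure.
#'
#' @param object An `ipn_sweep`.
#' @param y Summary column to plot (bare name or string). Default
#'   `"response"`.
#' @param x `"density"` or `"assortativity"`. Default `"density"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ipn_sweep
#' @export
autoplot.ipn_sweep <- function(object, y = "response",
                               x = c("density", "assortativity"), ...) {
  x <- match.arg(x)
  y <- rlang::as_name(rlang::enquo(y)) %||% "response"
  means <- tidy.ipn_sweep(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(colour = "grey55", alpha = 0.5) +
    ggplot2::geom_line(data = means, colour = "red", linewidth = 1) +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}
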