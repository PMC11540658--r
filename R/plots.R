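#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Orthographic scatter view of a point cloud
#'
#' @param object a [point_cloud()].
#' @param axes which two coordinates to plot (default x, z: the front
#'   view of an upright plant).
#' @param ... unused.
#' @return A ggplot with fixed aspect ratio; colored by the cloud's RGB
#'   when present, else by the third coordinate.
#' @method autoplot point_cloud
#' @export
autoplot.point_cloud <- function(object, axes = c("x", "z"), ...) {
  stopifnot(all(axes %in% c("x", "y", "z")), length(axes) == 2)
  third <- setdiff(c("x", "y", "z"), axes)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[axes[1]]],
                                    y = .data[[axes[2]]]))
  if (has_colors(object)) {
    p <- p + ggplot2::geom_point(
      color = grDevices::rgb(object$red, object$green, object$blue),
      size = 0.3)
  } else {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(color = .data[[third]]), size = 0.3) +
      ggplot2::scale_color_viridis_c()
  }
  p + ggplot2::coord_fixed() + ggplot2::theme_minimal() +
    ggplot2::labs(caption = sprintf(
      "%d points (%s)", nrow(object),
      if (is_metric(object)) "m" else "units"))
}

#' Front view of a skeleton graph with its measurement nodes
#'
#' @param object a `skeleton_graph`.
#' @param axes which two coordinates to plot.
#' @param ... unused.
#' @return A ggplot of tree edges with branch nodes (triangles) and end
#'   nodes (circles) overlaid.
#' @method autoplot skeleton_graph
#' @export
autoplot.skeleton_graph <- function(object, axes = c("x", "z"), ...) {
  ai <- match(axes, c("x", "y", "z"))
  seg <- tibble::tibble(
    x0 = object$nodes[object$edges$from, ai[1]],
    y0 = object$nodes[object$edges$from, ai[2]],
    x1 = object$nodes[object$edges$to, ai[1]],
    y1 = object$nodes[object$edges$to, ai[2]])
  nodes <- extract_node_positions(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      color = "grey40") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                   shape = .data$kind, color = .data$kind), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(branch = 17, end = 19)) +
    ggplot2::scale_color_manual(values = c(branch = "red", end = "blue")) +
    ggplot2::coord_fixed() + ggplot2::theme_minimal() +
    ggplot2::labs(x = axes[1], y = axes[2])
}
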