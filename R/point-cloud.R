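#' Construct a point cloud
#'
#' A point cloud is a tibble with columns `x`, `y`, `z` (and optionally
#' `red`, `green`, `blue` in \[0, 1\]) carrying an `is_metric` attribute.
#' Coordinates are in meters when `is_metric` is `TRUE`, otherwise in
#' arbitrary reconstruction units (e.g. raw structure-from-motion output).
#' Trait operations that report physical units refuse non-metric clouds so
#' that unit errors fail loudly rather than silently; see
#' [apply_scale()] for how a cloud becomes metric.
#'
#' @param points numeric matrix or data frame with 3 columns (x, y, z),
#'   or a numeric vector of length 3. Zero rows are allowed.
#' @param colors optional numeric matrix/data frame with 3 columns of
#'   RGB values in \[0, 1\], one row per point.
#' @param is_metric logical; `TRUE` when coordinates are meters.
#' @return A `point_cloud` tibble.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points = NULL, colors = NULL, is_metric = FALSE) {
  if (is.null(points)) {
    points <- matrix(numeric(0), ncol = 3)
  }
  if (is.vector(points) && is.numeric(points) && length(points) == 3L) {
    points <- matrix(points, ncol = 3)
  }
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3L) {
    stop("`points` must have exactly 3 columns (x, y, z), got ", ncol(points))
  }
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) {
    stop("point coordinates must all be finite")
  }
  df <- tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (ncol(colors) != 3L) stop("`colors` must have 3 columns (r, g, b)")
    if (nrow(colors) != nrow(points)) {
      stop("`colors` has ", nrow(colors), " rows but cloud has ",
           nrow(points), " points")
    }
    if (nrow(colors) > 0 && (min(colors) < 0 || max(colors) > 1)) {
      stop("colors must lie in [0, 1]")
    }
    df$red <- colors[, 1]
    df$green <- colors[, 2]
    df$blue <- colors[, 3]
  }
  new_point_cloud(df, is_metric = isTRUE(is_metric))
}

new_point_cloud <- function(df, is_metric = FALSE) {
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df <- tibble::as_tibble(df)
  class(df) <- c("point_cloud", class(tibble::tibble()))
  attr(df, "is_metric") <- isTRUE(is_metric)
  df
}

#' Coerce a data frame to a point cloud
#'
#' @param x data frame with columns `x`, `y`, `z` and optionally
#'   `red`, `green`, `blue`.
#' @param is_metric logical; defaults to the existing attribute if `x`
#'   already is a `point_cloud`, else `FALSE`.
#' @return A `point_cloud` tibble.
#' @export
as_point_cloud <- function(x, is_metric = NULL) {
  if (is.null(is_metric)) {
    is_metric <- isTRUE(attr(x, "is_metric"))
  }
  cols <- if (all(c("red", "green", "blue") %in% names(x))) {
    as.matrix(x[, c("red", "green", "blue")])
  } else {
    NULL
  }
  point_cloud(as.matrix(x[, c("x", "y", "z")]), colors = cols,
              is_metric = is_metric)
}

#' @export
print.point_cloud <- function(x, ...) {
  units <- if (is_metric(x)) "meters" else "reconstruction units"
  cat(sprintf("# point_cloud: %d points (%s)%s\n", nrow(x), units,
              if (has_colors(x)) ", RGB" else ""))
  NextMethod()
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud)

#' Is the cloud in metric units?
#' @param cloud a `point_cloud`.
#' @return Logical.
#' @export
is_metric <- function(cloud) isTRUE(attr(cloud, "is_metric"))

#' Does the cloud carry per-point colors?
#' @param cloud a `point_cloud`.
#' @return Logical.
#' @export
has_colors <- function(cloud) all(c("red", "green", "blue") %in% names(cloud))

# bare double matrix of coordinates, n x 3
pc_matrix <- function(cloud) {
  m <- cbind(cloud$x, cloud$y, cloud$z)
  colnames(m) <- c("x", "y", "z")
  m
}

pc_colors <- function(cloud) {
  if (!has_colors(cloud)) return(NULL)
  cbind(cloud$red, cloud$green, cloud$blue)
}

# replace coordinates, keep colors/attributes, preserve order
pc_replace_coords <- function(cloud, m) {
  stopifnot(nrow(m) == nrow(cloud))
  cloud$x <- m[, 1]
  cloud$y <- m[, 2]
  cloud$z <- m[, 3]
  cloud
}

require_metric <- function(cloud, what) {
  if (!is_metric(cloud)) {
    stop(what, " requires a metric cloud (is_metric = TRUE); ",
         "calibrate with estimate_scale()/apply_scale() first", call. = FALSE)
  }
  invisible(cloud)
}
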