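#' Crop regions
#'
#' Programmatic stand-ins for interactive point-cloud clipping: either an
#' axis-aligned box (bounds inclusive on both ends) or a polygon applied
#' to the orthographic projection of the cloud along a view direction
#' (points whose projection falls strictly inside the polygon are kept).
#'
#' @param min,max numeric length-3 lower/upper corner of the box.
#' @return A `crop_region` object for [crop_cloud()].
#' @examples
#' crop_region_box(c(0, 0, 0), c(1, 1, 1))
#' @export
crop_region_box <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  stopifnot(length(min) == 3, length(max) == 3)
  if (any(!is.finite(c(min, max)))) stop("box bounds must be finite")
  if (any(min > max)) stop("box min must be <= max on every axis")
  structure(list(kind = "box", min = min, max = max), class = "crop_region")
}

#' @rdname crop_region_box
#' @param vertices numeric matrix (>= 3 rows, 2 columns) of polygon
#'   vertices in the projection plane, in order.
#' @param view numeric length-3 view direction; points are projected
#'   orthographically along this axis onto its orthogonal plane.
#' @export
crop_region_polygon <- function(vertices, view = c(0, 0, 1)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("polygon needs >= 3 vertices with 2 columns (u, v)")
  }
  # reject fully collinear polygons (zero signed area)
  u <- vertices[, 1]; v <- vertices[, 2]
  area2 <- sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v)
  if (abs(area2) < .Machine$double.eps * max(1, max(abs(vertices)))^2) {
    stop("polygon vertices are collinear (zero area)")
  }
  view <- as.numeric(view)
  stopifnot(length(view) == 3)
  nv <- sqrt(sum(view^2))
  if (nv == 0) stop("view direction must be nonzero")
  structure(list(kind = "polygon", vertices = vertices, view = view / nv),
            class = "crop_region")
}

#' Crop a point cloud to a region
#'
#' Keeps exactly the points inside the region, carrying colors along and
#' preserving point order. Box bounds are inclusive; polygon containment
#' is strict on the projected coordinates. Cropping is idempotent and an
#' empty result is valid.
#'
#' @param cloud a [point_cloud()].
#' @param region a [crop_region_box()] or [crop_region_polygon()].
#' @return The cropped `point_cloud`.
#' @export
crop_cloud <- function(cloud, region) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(region, "crop_region"))
  m <- pc_matrix(cloud)
  keep <- if (region$kind == "box") {
    m[, 1] >= region$min[1] & m[, 1] <= region$max[1] &
      m[, 2] >= region$min[2] & m[, 2] <= region$max[2] &
      m[, 3] >= region$min[3] & m[, 3] <= region$max[3]
  } else {
    uv <- project_to_view_plane(m, region$view)
    points_in_polygon(uv, region$vertices)
  }
  cloud[keep, , drop = FALSE]
}

# orthonormal basis of the plane orthogonal to `view`; deterministic choice
view_plane_basis <- function(view) {
  a <- if (abs(view[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * view) * view
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    view[2] * e1[3] - view[3] * e1[2],
    view[3] * e1[1] - view[1] * e1[3],
    view[1] * e1[2] - view[2] * e1[1]
  )
  cbind(e1, e2)
}

project_to_view_plane <- function(m, view) {
  b <- view_plane_basis(view)
  m %*% b
}

# even-odd (ray casting) point-in-polygon, strict containment; vectorized
points_in_polygon <- function(uv, poly) {
  n <- nrow(uv)
  if (n == 0) return(logical(0))
  px <- poly[, 1]; py <- poly[, 2]
  np <- length(px)
  inside <- logical(n)
  x <- uv[, 1]; y <- uv[, 2]
  j <- np
  for (i in seq_len(np)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
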