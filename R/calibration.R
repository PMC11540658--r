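#' Marker observation for metric calibration
#'
#' A calibration marker of known physical size (e.g. a 30 cm x 30 cm
#' printed square placed in the scene) is reconstructed along with the
#' plant; matching its reconstructed edge lengths to the known physical
#' edge length yields the scale factor converting reconstruction units
#' to meters.
#'
#' @param corners numeric matrix (>= 2 rows, 3 columns) of reconstructed
#'   marker corner coordinates, in reconstruction units.
#' @param physical_edge_length physical edge length in meters
#'   (default 0.30, a 30 cm marker).
#' @param adjacency integer matrix with 2 columns: each row names a pair
#'   of corner indices joined by a physical marker edge. Defaults to the
#'   4 sides of a square when `corners` has 4 rows in order.
#' @return A `marker_observation` object.
#' @export
marker_observation <- function(corners, physical_edge_length = 0.30,
                               adjacency = NULL) {
  corners <- as.matrix(corners)
  storage.mode(corners) <- "double"
  if (ncol(corners) != 3 || nrow(corners) < 2) {
    stop("`corners` must be an n x 3 matrix with n >= 2")
  }
  if (any(!is.finite(corners))) stop("corner coordinates must be finite")
  if (physical_edge_length <= 0) stop("physical_edge_length must be > 0")
  if (is.null(adjacency)) {
    if (nrow(corners) == 4) {
      adjacency <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
    } else if (nrow(corners) == 2) {
      adjacency <- rbind(c(1, 2))
    } else {
      stop("supply `adjacency` when corners are not an ordered square")
    }
  }
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2 || nrow(adjacency) < 1) {
    stop("`adjacency` must have 2 columns and at least 1 row")
  }
  if (any(adjacency < 1 | adjacency > nrow(corners))) {
    stop("adjacency indices out of range")
  }
  d <- stats::dist(corners)
  if (any(d < .Machine$double.eps)) stop("marker corners must be pairwise distinct")
  structure(
    list(corners = corners, physical_edge_length = physical_edge_length,
         adjacency = adjacency),
    class = "marker_observation"
  )
}

#' Estimate the metric scale factor from a marker observation
#'
#' The scale factor (meters per reconstruction unit) is the mean over
#' marker edges of physical edge length / reconstructed edge length.
#' The residual RMS reports, in meters, the spread between the physical
#' edge length and each scaled reconstructed edge; for a noise-free
#' reconstruction it is zero. Edge-ratio averaging is invariant to rigid
#' motion of the reconstruction and needs no correspondence to a
#' canonical marker frame.
#'
#' @param obs a [marker_observation()].
#' @return A `scale_calibration` object with fields `scale_factor`,
#'   `residual_rms` (meters) and `marker_edge_m`.
#' @examples
#' obs <- marker_observation(rbind(c(0, 0, 0), c(1.5, 0, 0)),
#'                           physical_edge_length = 0.30)
#' estimate_scale(obs)$scale_factor  # 0.2 m per unit
#' @export
estimate_scale <- function(obs) {
  stopifnot(inherits(obs, "marker_observation"))
  e <- obs$adjacency
  d <- sqrt(rowSums((obs$corners[e[, 1], , drop = FALSE] -
                       obs$corners[e[, 2], , drop = FALSE])^2))
  if (any(d < 1e-12)) {
    stop("degenerate marker: zero-length reconstructed edge")
  }
  s <- mean(obs$physical_edge_length / d)
  resid <- obs$physical_edge_length - s * d
  structure(
    list(scale_factor = s,
         residual_rms = sqrt(mean(resid^2)),
         marker_edge_m = obs$physical_edge_length),
    class = "scale_calibration"
  )
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf(
    "# scale_calibration: %.9g m/unit (residual RMS %.3g m, marker edge %.3g m)\n",
    x$scale_factor, x$residual_rms, x$marker_edge_m))
  invisible(x)
}

#' Apply a scale calibration to a point cloud
#'
#' Multiplies every coordinate by the scale factor and marks the cloud
#' metric. Refuses already-metric clouds, guarding against accidental
#' double scaling.
#'
#' @param cloud a non-metric [point_cloud()].
#' @param cal a `scale_calibration` from [estimate_scale()], or a bare
#'   positive number of meters per reconstruction unit.
#' @return The metric `point_cloud`.
#' @export
apply_scale <- function(cloud, cal) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is_metric(cloud)) {
    stop("cloud is already metric; refusing to scale twice")
  }
  s <- if (inherits(cal, "scale_calibration")) cal$scale_factor else as.numeric(cal)
  if (!is.finite(s) || s <= 0) stop("scale factor must be a positive number")
  out <- pc_replace_coords(cloud, pc_matrix(cloud) * s)
  attr(out, "is_metric") <- TRUE
  attr(out, "scale_factor") <- s
  out
}

#' Persist / load a scale calibration as JSON
#'
#' @param cal a `scale_calibration`.
#' @param path JSON file path.
#' @return `write_calibration`: `path` invisibly; `read_calibration`:
#'   the `scale_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "scale_calibration"))
  jsonlite::write_json(
    list(scale_factor = cal$scale_factor, residual_rms = cal$residual_rms,
         marker_edge_m = cal$marker_edge_m),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$scale_factor) || x$scale_factor <= 0) {
    stop("invalid calibration file: ", path)
  }
  structure(
    list(scale_factor = x$scale_factor,
         residual_rms = x$residual_rms %||% NA_real_,
         marker_edge_m = x$marker_edge_m %||% NA_real_),
    class = "scale_calibration"
  )
}
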