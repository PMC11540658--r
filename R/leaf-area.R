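#' Leaf area from a segmented leaf point cloud
#'
#' Full leaf stage: moving-least-squares smoothing collapses surface
#' noise onto the leaf sheet, ball pivoting meshes it, and the area is
#' the sum of triangle areas. Leaves are open surfaces, so the mesh is
#' not required to be watertight; the reported area is the single-sided
#' reconstructed-surface area. Diagnostics include the fraction of
#' points used by the mesh — a low fraction signals under-reconstruction
#' (holes where sampling was too sparse or one-sided).
#'
#' @param cloud a metric, segmented single-leaf [point_cloud()].
#' @param mls an [mls_params()].
#' @param bpa a [bpa_params()].
#' @return List with `area_m2`, `area_cm2`, `mesh` (the
#'   [triangle_mesh()]) and `diagnostics` (tibble: `n_points`,
#'   `n_faces`, `vertex_usage`, `n_sparse`).
#' @export
leaf_area_pipeline <- function(cloud, mls = mls_params(), bpa = bpa_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("empty segmented leaf cloud")
  require_metric(cloud, "leaf area")
  smoothed <- mls_smooth(cloud, mls)
  mesh <- bpa_reconstruct(smoothed, bpa)
  area <- mesh_area(mesh)
  used <- attr(mesh, "vertex_used")
  diagnostics <- tibble::tibble(
    n_points = n_points(cloud),
    n_faces = nrow(mesh$faces),
    vertex_usage = mean(used),
    n_sparse = sum(attr(smoothed, "sparse_flags") %||% FALSE)
  )
  list(area_m2 = area, area_cm2 = area * 1e4, mesh = mesh,
       diagnostics = diagnostics)
}
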