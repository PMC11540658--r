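#' Parameters for moving-least-squares smoothing
#'
#' @param search_radius neighborhood radius in meters; `NULL` (default)
#'   derives 4x the median nearest-neighbor distance of the input cloud.
#' @param polynomial_order 1 (plane) or 2 (quadric; default — preserves
#'   leaf curvature).
#' @param kernel_bandwidth Gaussian weight scale in meters; `NULL`
#'   derives `search_radius / 2`.
#' @param min_neighbors minimum neighborhood size to attempt a fit;
#'   must be at least the polynomial coefficient count (3 for order 1,
#'   6 for order 2). Default 8.
#' @return An `mls_params` list.
#' @export
mls_params <- function(search_radius = NULL, polynomial_order = 2,
                       kernel_bandwidth = NULL, min_neighbors = 8) {
  if (!polynomial_order %in% c(1, 2)) stop("polynomial_order must be 1 or 2")
  ncoef <- if (polynomial_order == 1) 3L else 6L
  if (min_neighbors < ncoef) {
    stop("min_neighbors must be >= ", ncoef, " for order ", polynomial_order)
  }
  if (!is.null(search_radius) && search_radius <= 0) {
    stop("search_radius must be > 0")
  }
  structure(
    list(search_radius = search_radius,
         polynomial_order = as.integer(polynomial_order),
         kernel_bandwidth = kernel_bandwidth,
         min_neighbors = as.integer(min_neighbors)),
    class = "mls_params"
  )
}

#' Smooth a point cloud by moving-least-squares projection
#'
#' Each point is projected onto the local weighted-least-squares
#' polynomial surface fitted to its radius neighborhood: the
#' neighborhood's principal plane supplies a local frame, a polynomial
#' height field is fitted with Gaussian weights, and the point moves to
#' its height on that surface. Points with fewer than `min_neighbors`
#' neighbors pass through unchanged and are flagged sparse. Point count
#' and order are preserved.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param params an [mls_params()].
#' @return The smoothed `point_cloud` with attribute `sparse_flags`
#'   (logical per point: `TRUE` where the point passed through
#'   unsmoothed). A warning is raised if every point was sparse.
#' @export
mls_smooth <- function(cloud, params = mls_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("cannot smooth an empty cloud")
  m <- pc_matrix(cloud)
  n <- nrow(m)
  radius <- params$search_radius
  if (is.null(radius)) {
    mnn <- median_nn_distance(m)
    if (!is.finite(mnn) || mnn == 0) mnn <- 1e-3
    radius <- 4 * mnn
  }
  h <- params$kernel_bandwidth %||% (radius / 2)
  order <- params$polynomial_order
  ncoef <- if (order == 1) 3L else 6L

  k_cap <- min(n, 192L)
  nn <- RANN::nn2(m, k = k_cap, searchtype = "radius", radius = radius)
  out <- m
  sparse <- logical(n)
  for (i in seq_len(n)) {
    ids <- nn$nn.idx[i, ]
    ids <- ids[ids > 0L]
    if (length(ids) < params$min_neighbors) {
      sparse[i] <- TRUE
      next
    }
    nb <- m[ids, , drop = FALSE]
    ctr <- colMeans(nb)
    q <- sweep(nb, 2, ctr)
    ev <- eigen(crossprod(q), symmetric = TRUE)
    e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]; nrm <- ev$vectors[, 3]
    u <- q %*% e1; v <- q %*% e2; w <- q %*% nrm
    d2 <- rowSums(q^2)
    wt <- exp(-d2 / (2 * h^2))
    X <- if (order == 1) cbind(1, u, v) else cbind(1, u, v, u^2, u * v, v^2)
    XtW <- t(X * wt)
    coef <- tryCatch(solve(XtW %*% X, XtW %*% w),
                     error = function(e) NULL)
    if (is.null(coef)) {
      sparse[i] <- TRUE
      next
    }
    p <- m[i, ] - ctr
    ui <- sum(p * e1); vi <- sum(p * e2)
    xi <- if (order == 1) c(1, ui, vi) else c(1, ui, vi, ui^2, ui * vi, vi^2)
    wi <- sum(xi * coef)
    out[i, ] <- ctr + ui * e1 + vi * e2 + wi * nrm
  }
  if (all(sparse)) {
    warning("all points too sparse for MLS; cloud returned unchanged")
  }
  res <- pc_replace_coords(cloud, out)
  attr(res, "sparse_flags") <- sparse
  attr(res, "search_radius") <- radius
  res
}
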