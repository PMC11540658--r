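#' Align a point cloud to its principal frame
#'
#' Estimates the body center and rotates the cloud onto the principal
#' axes of the point covariance about that center (right-handed,
#' ordered by descending variance) — the pose in which an axis-aligned
#' ellipsoid is fitted. The center is the algebraic least-squares
#' sphere center (linear in the parameters, deterministic): for a
#' partially observed fruit the plain centroid sits in the middle of
#' the observed cap, far from the body center, which would wreck the
#' subsequent fit; the sphere center is exact for spherical caps and
#' close for the mildly eccentric shapes of fruit. When the sphere
#' system is ill-conditioned (near-planar clouds) the centroid is used.
#'
#' @param cloud a [point_cloud()] with >= 10 points, not all coplanar.
#' @return List with `aligned` (the rotated, centered `point_cloud`),
#'   `center` (length-3), and `orientation` (3 x 3 rotation, fit frame
#'   to world: `world = center + orientation %*% local`).
#' @export
align_to_principal_frame <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  m <- pc_matrix(cloud)
  if (nrow(m) < 10) stop("need at least 10 points, got ", nrow(m))
  ctr <- sphere_center(m)
  cm <- sweep(m, 2, ctr)
  cv <- crossprod(cm) / max(1, nrow(m) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  sdev <- sqrt(pmax(eg$values, 0))
  if (sdev[3] < 1e-9 * max(sdev[1], 1e-300)) {
    stop("degenerate covariance (points coplanar or collinear)")
  }
  ax <- eg$vectors
  for (j in 1:2) {
    k <- which.max(abs(ax[, j]))
    if (ax[k, j] < 0) ax[, j] <- -ax[, j]
  }
  ax[, 3] <- cross3(ax[, 1], ax[, 2])
  list(aligned = pc_replace_coords(cloud, cm %*% ax),
       center = unname(ctr), orientation = unname(ax))
}

# algebraic least-squares sphere center: |p|^2 = 2 c.p + d is linear in
# (c, d); falls back to the centroid when ill-conditioned
sphere_center <- function(m) {
  centroid <- colMeans(m)
  A <- cbind(2 * m, 1)
  b <- rowSums(m^2)
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) return(centroid)
  ctr <- unname(fit[1:3])
  # reject wild extrapolations (quasi-planar patches send the center
  # to infinity); the cloud's own extent bounds a plausible center
  spread <- max(apply(m, 2, function(v) diff(range(v))))
  if (sqrt(sum((ctr - centroid)^2)) > 2 * spread) return(centroid)
  ctr
}

# objective of the algebraic ellipsoid fit and its residual vector in
# log-semi-axis parameterization
ellipsoid_residuals <- function(theta, sq) {
  inv <- exp(-2 * theta)  # 1/a^2, 1/b^2, 1/c^2
  drop(sq %*% inv) - 1
}

ellipsoid_jacobian <- function(theta, sq) {
  inv <- exp(-2 * theta)
  -2 * sweep(sq, 2, inv, `*`)
}

#' Fit an axis-aligned ellipsoid by least squares
#'
#' Estimates semi-axes (a, b, c) minimizing the algebraic objective
#' \deqn{f(a,b,c) = \sum_{i=1}^{M} \left(\frac{x_i^2}{a^2} +
#'   \frac{y_i^2}{b^2} + \frac{z_i^2}{c^2} - 1\right)^2}
#' over a centered, axis-aligned cloud. Optimization runs in
#' (log a, log b, log c) — positivity without constraints — with
#' analytic Jacobian under Levenberg-Marquardt, initialized from the
#' per-axis maximum absolute coordinate (or `init`). The ellipsoid
#' volume is \eqn{V = \frac{4}{3}\pi a b c}.
#'
#' @param aligned a centered [point_cloud()] (>= 10 points), e.g. from
#'   [align_to_principal_frame()].
#' @param init optional numeric length-3 starting semi-axes.
#' @param center,orientation pose to record on the fit (defaults:
#'   origin / identity).
#' @param refine_center after the semi-axis fit, re-minimize the same
#'   objective jointly over semi-axes, a center offset and a small
#'   rotation (9 parameters). With partial angular coverage the
#'   up-front pose estimate is the dominant error source — the sphere
#'   center is biased for eccentric shapes and the covariance
#'   eigenvectors degenerate when the observed cap is nearly isotropic
#'   — and pose refinement keeps half-coverage volume errors bounded.
#'   The refined world-frame pose is recorded on the fit. Default
#'   `FALSE` (the plain fixed-pose fit).
#' @return An `ellipsoid_fit`: `center`, `orientation`, `semi_axes`,
#'   `residual` (objective at the optimum), `volume` (m^3 for metric
#'   input), `n_points`, `convergence` (optimizer message).
#' @export
fit_ellipsoid <- function(aligned, init = NULL, center = c(0, 0, 0),
                          orientation = diag(3), refine_center = FALSE) {
  stopifnot(inherits(aligned, "point_cloud"))
  m <- pc_matrix(aligned)
  if (nrow(m) < 10) stop("need at least 10 points, got ", nrow(m))
  sq <- m^2
  if (is.null(init)) {
    init <- apply(abs(m), 2, max)
  }
  init <- as.numeric(init)
  if (length(init) != 3 || any(!is.finite(init)) || any(init <= 0)) {
    stop("init must be 3 positive finite semi-axes")
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                    ptol = 1e-12)
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = log(init),
    fn = ellipsoid_residuals,
    jac = ellipsoid_jacobian,
    sq = sq,
    control = ctl
  ))
  theta <- fit$par
  if (any(!is.finite(theta))) {
    stop("ellipsoid fit failed: non-finite iterate (info = ", fit$info,
         ", message: ", fit$message, ")")
  }
  center <- as.numeric(center)
  if (refine_center) {
    # joint pose refinement: semi-axes + center offset + small rotation
    # (XYZ Euler composition), same algebraic objective
    euler <- function(w) {
      cx <- cos(w[1]); sx <- sin(w[1])
      cy <- cos(w[2]); sy <- sin(w[2])
      cz <- cos(w[3]); sz <- sin(w[3])
      rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
      ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
      rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
      rx %*% ry %*% rz
    }
    fn9 <- function(p) {
      q <- sweep(m, 2, p[4:6]) %*% euler(p[7:9])
      drop((q^2) %*% exp(-2 * p[1:3])) - 1
    }
    fit9 <- suppressWarnings(minpack.lm::nls.lm(
      par = c(theta, rep(0, 6)), fn = fn9, control = ctl))
    if (all(is.finite(fit9$par))) {
      theta <- fit9$par[1:3]
      offset <- fit9$par[4:6]
      rot <- euler(fit9$par[7:9])
      center <- center + drop(orientation %*% offset)
      orientation <- orientation %*% rot
      m <- sweep(m, 2, offset) %*% rot
      sq <- m^2
      fit <- fit9
    }
  }
  axes <- exp(theta)
  resid <- sum(ellipsoid_residuals(theta, sq)^2)
  if (!is.finite(resid)) stop("ellipsoid fit failed: non-finite objective")
  structure(
    list(center = center, orientation = orientation,
         semi_axes = axes, residual = resid,
         volume = 4 / 3 * pi * prod(axes),
         n_points = nrow(m), convergence = fit$message),
    class = "ellipsoid_fit"
  )
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf(
    "# ellipsoid_fit: semi-axes (%.4g, %.4g, %.4g), volume %.6g, residual %.3g (n = %d)\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$volume, x$residual,
    x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ellipsoid fit
#'
#' @param x an `ellipsoid_fit`.
#' @param ... unused.
#' @return One row per semi-axis: `term`, `estimate` (meters),
#'   `estimate_mm`.
#' @method tidy ellipsoid_fit
#' @export
tidy.ellipsoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = x$semi_axes,
    estimate_mm = x$semi_axes * 1e3
  )
}

#' Glance at an ellipsoid fit
#'
#' @param x an `ellipsoid_fit`.
#' @param ... unused.
#' @return One-row tibble: `volume_m3`, `volume_cm3`, `residual`,
#'   `n_points`.
#' @method glance ellipsoid_fit
#' @export
glance.ellipsoid_fit <- function(x, ...) {
  tibble::tibble(
    volume_m3 = x$volume,
    volume_cm3 = x$volume * 1e6,
    residual = x$residual,
    n_points = x$n_points
  )
}

# fraction of the direction sphere (around `center`) covered by observed
# points, on a Fibonacci-lattice binning
coverage_fraction <- function(m, center, n_bins = 64) {
  d <- sweep(m, 2, center)
  nr <- sqrt(rowSums(d^2))
  ok <- nr > 0
  if (!any(ok)) return(0)
  dirs <- d[ok, , drop = FALSE] / nr[ok]
  i <- seq_len(n_bins) - 0.5
  phi <- acos(1 - 2 * i / n_bins)
  theta <- pi * (1 + sqrt(5)) * i
  lattice <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  hit <- unique(max.col(dirs %*% t(lattice)))
  length(hit) / n_bins
}

#' Fruit volume from a segmented fruit point cloud
#'
#' Full fruit stage: principal-frame alignment, algebraic ellipsoid
#' least squares, volume in cm^3. Fitting an ellipsoid to the observed
#' cap extrapolates the unobserved rear of a partially captured fruit
#' under a symmetry assumption; the `coverage` diagnostic (fraction of
#' viewing directions populated, estimated from the fitted center) lets
#' downstream users filter unreliable fits.
#'
#' @param cloud a metric, segmented single-fruit [point_cloud()]
#'   (>= 10 points).
#' @param init optional starting semi-axes passed to [fit_ellipsoid()].
#' @return List with `fit` (the `ellipsoid_fit`, pose recorded in world
#'   coordinates), `volume_cm3`, and `coverage` in \[0, 1\].
#' @export
fruit_volume_pipeline <- function(cloud, init = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  require_metric(cloud, "fruit volume")
  al <- align_to_principal_frame(cloud)
  fit <- fit_ellipsoid(al$aligned, init = init, center = al$center,
                       orientation = al$orientation, refine_center = TRUE)
  cov <- coverage_fraction(pc_matrix(cloud), fit$center)
  list(fit = fit, volume_cm3 = fit$volume * 1e6, coverage = cov)
}

#' Triangulated surface of a fitted ellipsoid (for visual QC export)
#'
#' @param fit an `ellipsoid_fit`.
#' @param n_theta,n_phi longitudinal / latitudinal resolution.
#' @return A [triangle_mesh()] in world coordinates.
#' @export
ellipsoid_mesh <- function(fit, n_theta = 24, n_phi = 12) {
  stopifnot(inherits(fit, "ellipsoid_fit"))
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)
  grid <- expand.grid(th = th, ph = ph)
  local <- cbind(
    fit$semi_axes[1] * sin(grid$ph) * cos(grid$th),
    fit$semi_axes[2] * sin(grid$ph) * sin(grid$th),
    fit$semi_axes[3] * cos(grid$ph)
  )
  world <- sweep(local %*% t(fit$orientation), 2, fit$center, `+`)
  idx <- function(i, j) (j - 1L) * n_theta + i  # i: theta, j: phi row
  faces <- list()
  for (j in seq_len(n_phi)) {
    for (i in seq_len(n_theta)) {
      i2 <- if (i == n_theta) 1L else i + 1L
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i2, j), idx(i, j + 1L))
      faces[[length(faces) + 1L]] <- c(idx(i2, j), idx(i2, j + 1L), idx(i, j + 1L))
    }
  }
  f <- do.call(rbind, faces)
  keep <- f[, 1] != f[, 2] & f[, 1] != f[, 3] & f[, 2] != f[, 3]
  triangle_mesh(world, f[keep, , drop = FALSE])
}
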