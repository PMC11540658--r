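#' Synthetic plant-organ fixtures
#'
#' Seeded generators of organ point clouds with exact analytic ground
#' truth, emulating the capture geometry of forward-facing
#' reconstruction (dense on the camera-facing side, sparse or absent
#' behind). Every truth value is computed in closed form from the
#' generator parameters, never measured from the generated cloud, so
#' the generators can serve as an oracle for the trait pipeline.
#' Regenerating with the same seed and parameters reproduces the
#' identical cloud bit for bit (single RNG stream per fixture; the RNG
#' algorithm is pinned in the fixture metadata).
#'
#' @name synthetic_fixtures
NULL

fixture_capture <- function(view = NULL, coverage = 1, noise_sd = 0,
                            density = NA_real_) {
  list(view = view, coverage = coverage, noise_sd = noise_sd,
       density = density, rng = "Mersenne-Twister")
}

new_plant_fixture <- function(cloud, truth, seed, capture) {
  structure(list(cloud = cloud, truth = truth, seed = seed,
                 capture = capture),
            class = "plant_fixture")
}

#' @export
print.plant_fixture <- function(x, ...) {
  cat(sprintf("# plant_fixture: %d points, seed %d; truth: %s\n",
              n_points(x$cloud), x$seed,
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

# area-uniform samples on a cylinder side wall (axis +z from z0)
sample_tube <- function(n, radius, length, z0 = 0) {
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, 0, length)
  cbind(radius * cos(th), radius * sin(th), z0 + z)
}

add_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  m + matrix(stats::rnorm(length(m), sd = sd), nrow(m), 3)
}

#' Generate a synthetic stem with lateral branches
#'
#' A vertical stem tube carries lateral branch tubes at cumulative
#' heights; the anatomical nodes (branch divergence points) are the
#' ground-truth landmarks and consecutive node spacings are the true
#' inter-node lengths. Branch azimuths follow a golden-angle phyllotaxy
#' and branches rise slightly above horizontal.
#'
#' @param node_spacings inter-node distances in meters (all > 0).
#' @param stem_radius,branch_radius tube radii in meters.
#' @param branch_length branch tube length in meters.
#' @param density surface sampling density, points per m^2; each organ
#'   tube gets at least `min_organ_points` points.
#' @param min_organ_points floor on points per tube (default 500).
#' @param noise_sd isotropic Gaussian surface noise, meters.
#' @param seed integer seed.
#' @param margin stem length below the first / above the last node.
#' @return A `plant_fixture` with a metric cloud and truth
#'   `node_positions` (matrix) and `inter_node_distances`
#'   (= `node_spacings`).
#' @export
generate_stem <- function(node_spacings = c(0.10, 0.25, 0.40),
                          stem_radius = 0.008, branch_radius = 0.005,
                          branch_length = 0.06, density = 6e4,
                          min_organ_points = 500, noise_sd = 0.002,
                          seed = 1, margin = 0.08) {
  if (any(node_spacings <= 0)) stop("node spacings must be > 0")
  if (stem_radius <= 0 || branch_radius <= 0 || branch_length <= 0) {
    stop("radii and branch_length must be > 0")
  }
  node_z <- margin + cumsum(c(0, node_spacings))
  stem_len <- max(node_z) + margin
  withr::with_seed(seed, {
    n_stem <- max(min_organ_points,
                  round(density * 2 * pi * stem_radius * stem_len))
    pts <- list(sample_tube(n_stem, stem_radius, stem_len))
    golden <- pi * (3 - sqrt(5))
    elev <- 15 * pi / 180
    for (i in seq_along(node_z)) {
      az <- (i - 1) * golden
      dir <- c(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev))
      n_br <- max(min_organ_points,
                  round(density * 2 * pi * branch_radius * branch_length))
      tube <- sample_tube(n_br, branch_radius, branch_length)
      # rotate tube axis (+z) onto `dir`, then attach at the node
      R <- rotation_from_z(dir)
      pts[[i + 1L]] <- sweep(tube %*% t(R), 2, c(0, 0, node_z[i]), `+`)
    }
    m <- add_noise(do.call(rbind, pts), noise_sd)
  })
  truth <- list(
    node_positions = cbind(0, 0, node_z),
    inter_node_distances = node_spacings
  )
  new_plant_fixture(point_cloud(m, is_metric = TRUE), truth, seed,
                    fixture_capture(noise_sd = noise_sd, density = density))
}

# rotation taking +z to unit vector d
rotation_from_z <- function(d) {
  d <- normalize3(d)
  z <- c(0, 0, 1)
  v <- cross3(z, d)
  c_ <- sum(z * d)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

s_curl_curve <- function(t, R, psi) {
  # S-shaped plane curve: constant curvature +1/R then -1/R, arc-length
  # parameterized; heading rises 0 -> psi then falls back to 0
  L1 <- R * psi
  h <- ifelse(t <= L1, t / R, psi - (t - L1) / R)
  x <- ifelse(t <= L1, R * sin(h), R * sin(psi) + R * (sin(psi) - sin(h)))
  z <- ifelse(t <= L1, R * (1 - cos(h)),
              R * (1 - cos(psi)) + R * (cos(h) - cos(psi)))
  list(x = x, z = z, heading = h)
}

#' Generate a synthetic leaf surface
#'
#' Parametric leaf surfaces sampled uniformly by area, with analytic
#' ground-truth area: a flat disc (area `pi r^2`), a half-cylinder shell
#' (area `pi r h`), or an s-curl — a sheet extruded from an S-shaped
#' curve of two equal circular arcs (closed-form length `2 R psi`, area
#' `2 R psi * width`) that mimics a curled leaf. With
#' `one_sided = TRUE`, points whose surface normal faces away from
#' `view` are dropped, emulating the far side of a curl that a
#' forward-facing capture misses; the truth area still refers to the
#' full surface.
#'
#' @param shape `"flat-disc"`, `"half-cylinder"` or `"s-curl"`.
#' @param disc_radius disc radius (m).
#' @param cyl_radius,cyl_height half-cylinder radius and height (m).
#' @param curl_radius,curl_angle,curl_width s-curl arc radius (m), arc
#'   turn angle (rad, per arc) and extrusion width (m).
#' @param density points per m^2.
#' @param noise_sd isotropic Gaussian noise (m).
#' @param seed integer seed.
#' @param one_sided drop far-facing points (see above).
#' @param view capture view direction (used when `one_sided`).
#' @return A `plant_fixture` with truth `leaf_area` (m^2).
#' @export
generate_leaf <- function(shape = c("flat-disc", "half-cylinder", "s-curl"),
                          disc_radius = 0.05, cyl_radius = 0.05,
                          cyl_height = 0.12, curl_radius = 0.03,
                          curl_angle = 2.0, curl_width = 0.08,
                          density = 2e5, noise_sd = 5e-4, seed = 1,
                          one_sided = FALSE, view = c(0, 0, 1)) {
  shape <- match.arg(shape)
  if (density <= 0) stop("density must be > 0")
  res <- withr::with_seed(seed, switch(shape,
    "flat-disc" = {
      if (disc_radius <= 0) stop("disc_radius must be > 0")
      area <- pi * disc_radius^2
      n <- max(200, round(density * area))
      r <- disc_radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      list(m = cbind(r * cos(th), r * sin(th), 0),
           normals = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE),
           area = area)
    },
    "half-cylinder" = {
      if (cyl_radius <= 0 || cyl_height <= 0) stop("cylinder dims must be > 0")
      area <- pi * cyl_radius * cyl_height
      n <- max(200, round(density * area))
      th <- stats::runif(n, 0, pi)
      y <- stats::runif(n, 0, cyl_height)
      list(m = cbind(cyl_radius * cos(th), y, cyl_radius * sin(th)),
           normals = cbind(cos(th), 0, sin(th)),
           area = area)
    },
    "s-curl" = {
      if (curl_radius <= 0 || curl_angle <= 0 || curl_angle >= pi ||
            curl_width <= 0) {
        stop("curl parameters out of domain (need 0 < curl_angle < pi)")
      }
      L <- 2 * curl_radius * curl_angle
      area <- L * curl_width
      n <- max(200, round(density * area))
      t <- stats::runif(n, 0, L)
      y <- stats::runif(n, 0, curl_width)
      cv <- s_curl_curve(t, curl_radius, curl_angle)
      list(m = cbind(cv$x, y, cv$z),
           normals = cbind(-sin(cv$heading), 0, cos(cv$heading)),
           area = area)
    }
  ))
  m <- res$m
  normals <- res$normals
  if (one_sided) {
    view <- normalize3(view)
    keep <- drop(normals %*% view) >= 0
    m <- m[keep, , drop = FALSE]
  }
  m <- withr::with_seed(seed + 1L, add_noise(m, noise_sd))
  new_plant_fixture(
    point_cloud(m, is_metric = TRUE),
    list(leaf_area = res$area, shape = shape),
    seed,
    fixture_capture(view = if (one_sided) view else NULL,
                    coverage = if (one_sided) 0.5 else 1,
                    noise_sd = noise_sd, density = density))
}

#' Generate a synthetic fruit (ellipsoid surface) with partial coverage
#'
#' Samples the ellipsoid surface uniformly by area (rejection sampling
#' with the exact area-element weight), then keeps the points whose
#' outward normal lies within the angular cap around `view` that covers
#' `coverage` of the normal sphere — the occlusion pattern of a fruit
#' imaged from limited angles. Truth volume is `(4/3) pi a b c`.
#'
#' @param semi_axes numeric length-3 (a, b, c) in meters.
#' @param coverage fraction of the normal sphere observed, in (0, 1].
#' @param view capture view direction.
#' @param n_points full-surface sample count before the coverage cut.
#' @param noise_sd isotropic Gaussian noise (m).
#' @param seed integer seed.
#' @param center translation applied to the fruit (m).
#' @param rotation optional 3 x 3 rotation applied to the fruit.
#' @return A `plant_fixture` with truth `semi_axes` and
#'   `fruit_volume` (m^3).
#' @export
generate_fruit <- function(semi_axes = c(0.040, 0.030, 0.030),
                           coverage = 1, view = c(1, 0, 0),
                           n_points = 1500, noise_sd = 5e-4, seed = 1,
                           center = c(0, 0, 0), rotation = NULL) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(semi_axes <= 0)) {
    stop("semi_axes must be 3 positive numbers")
  }
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  a <- semi_axes[1]; b <- semi_axes[2]; c_ <- semi_axes[3]
  view <- normalize3(view)
  m <- withr::with_seed(seed, {
    got <- matrix(numeric(0), ncol = 3)
    nrm <- matrix(numeric(0), ncol = 3)
    wmax <- max(b * c_, a * c_, a * b)
    while (nrow(got) < n_points) {
      nb <- 4L * (n_points - nrow(got)) + 64L
      u <- matrix(stats::rnorm(3L * nb), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      w <- sqrt((u[, 1] * b * c_)^2 + (u[, 2] * a * c_)^2 +
                  (u[, 3] * a * b)^2)
      acc <- stats::runif(nb) < w / wmax
      got <- rbind(got, cbind(a * u[acc, 1], b * u[acc, 2], c_ * u[acc, 3]))
      nrm <- rbind(nrm, u[acc, , drop = FALSE])
    }
    got <- got[seq_len(n_points), , drop = FALSE]
    nrm <- nrm[seq_len(n_points), , drop = FALSE]
    # outward normal of the ellipsoid at (a u1, b u2, c u3)
    normals <- cbind(nrm[, 1] / a, nrm[, 2] / b, nrm[, 3] / c_)
    normals <- normals / sqrt(rowSums(normals^2))
    if (coverage < 1) {
      cos_alpha <- 1 - 2 * coverage  # cap of the normal sphere
      keep <- drop(normals %*% view) >= cos_alpha
      got <- got[keep, , drop = FALSE]
    }
    if (!is.null(rotation)) got <- got %*% t(rotation)
    got <- sweep(got, 2, center, `+`)
    add_noise(got, noise_sd)
  })
  new_plant_fixture(
    point_cloud(m, is_metric = TRUE),
    list(semi_axes = semi_axes,
         fruit_volume = 4 / 3 * pi * prod(semi_axes)),
    seed,
    fixture_capture(view = view, coverage = coverage, noise_sd = noise_sd))
}

#' Generate a synthetic calibration-marker observation
#'
#' Corners of a square marker of physical edge `edge_m` expressed in
#' "reconstruction units" (`scale` units per meter), optionally rotated,
#' translated and perturbed. Truth scale factor is `1 / scale` meters
#' per unit.
#'
#' @param scale reconstruction units per meter (> 0).
#' @param rotation optional 3 x 3 rotation (default: seeded random).
#' @param translation length-3 offset in reconstruction units.
#' @param corner_noise_sd Gaussian corner noise in reconstruction units.
#' @param seed integer seed.
#' @param edge_m physical marker edge length in meters.
#' @return List with `observation` (a [marker_observation()]), `truth`
#'   (`scale_factor = 1/scale`) and `seed`.
#' @export
generate_marker <- function(scale = 5, rotation = NULL,
                            translation = c(0, 0, 0), corner_noise_sd = 0,
                            seed = 1, edge_m = 0.30) {
  if (scale <= 0) stop("scale must be > 0")
  corners_m <- rbind(c(0, 0, 0), c(edge_m, 0, 0), c(edge_m, edge_m, 0),
                     c(0, edge_m, 0))
  corners <- withr::with_seed(seed, {
    R <- rotation %||% random_rotation()
    x <- scale * corners_m %*% t(R)
    x <- sweep(x, 2, translation, `+`)
    if (corner_noise_sd > 0) {
      x <- x + matrix(stats::rnorm(12, sd = corner_noise_sd), 4, 3)
    }
    x
  })
  list(observation = marker_observation(corners, physical_edge_length = edge_m),
       truth = list(scale_factor = 1 / scale),
       seed = seed)
}

#' Write a fixture to disk (PLY + truth JSON side by side)
#'
#' @param fixture a `plant_fixture`.
#' @param dir output directory (created if needed).
#' @param name file stem; writes `<name>.ply`, `<name>.ply.json` and
#'   `<name>_truth.json`.
#' @return Invisibly, the PLY path.
#' @export
write_fixture <- function(fixture, dir, name) {
  stopifnot(inherits(fixture, "plant_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ply <- file.path(dir, paste0(name, ".ply"))
  write_point_cloud(fixture$cloud, ply)
  jsonlite::write_json(
    list(truth = fixture$truth, seed = fixture$seed,
         capture = fixture$capture),
    file.path(dir, paste0(name, "_truth.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(ply)
}

#' Materialize the standard fixture suite
#'
#' One stem, three leaves (one per shape) and two fruits (full and
#' 60 percent coverage), written via [write_fixture()].
#'
#' @param dir output directory.
#' @param seed base seed; sub-fixtures use fixed offsets from it.
#' @return Tibble of fixture names and paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1) {
  fixtures <- list(
    stem = generate_stem(seed = seed),
    leaf_disc = generate_leaf("flat-disc", seed = seed + 1L),
    leaf_halfcyl = generate_leaf("half-cylinder", seed = seed + 2L),
    leaf_scurl = generate_leaf("s-curl", seed = seed + 3L),
    fruit_full = generate_fruit(seed = seed + 4L),
    fruit_part = generate_fruit(coverage = 0.6, seed = seed + 5L)
  )
  paths <- vapply(names(fixtures), function(nm) {
    write_fixture(fixtures[[nm]], dir, nm)
  }, character(1))
  invisible(tibble::tibble(name = names(fixtures), path = unname(paths)))
}
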