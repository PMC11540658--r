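test_that("points on a plane are fixed under MLS", {
  set.seed(5)
  pc <- point_cloud(cbind(runif(800, 0, 0.1), runif(800, 0, 0.1), 0))
  sm <- mls_smooth(pc)
  expect_lt(max(abs(cbind(sm$x, sm$y, sm$z) - cbind(pc$x, pc$y, pc$z))),
            1e-9)
})

test_that("MLS collapses sigma = 2 mm plane noise below 0.5 mm RMS", {
  set.seed(6)
  n <- 1500
  pc <- point_cloud(cbind(runif(n, 0, 0.1), runif(n, 0, 0.1),
                          rnorm(n, 0, 0.002)))
  # the search radius must resolve the noise amplitude (~10 sigma)
  sm <- mls_smooth(pc, mls_params(search_radius = 0.02))
  expect_lt(sqrt(mean(sm$z^2)), 5e-4)
})

test_that("sparse points pass through unchanged and are flagged", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(10, 10, 10)))
  expect_warning(sm <- mls_smooth(pc, mls_params(search_radius = 0.1)),
                 "sparse")
  expect_cloud_equal(sm, pc)
  expect_true(all(attr(sm, "sparse_flags")))
  expect_error(mls_smooth(point_cloud()), "empty")
  expect_error(mls_params(polynomial_order = 3), "1 or 2")
  expect_error(mls_params(polynomial_order = 2, min_neighbors = 4), ">= 6")
})

test_that("mesh_area sums triangle areas with the expected properties", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(mesh_area(sq), 1.0)
  # degenerate (collinear) triangle contributes zero
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(1, 2, 3)))
  expect_equal(mesh_area(degen), 0)
  # similarity scaling law: area scales with k^2
  k <- 3.7
  sq_k <- triangle_mesh(sq$vertices * k, sq$faces)
  expect_equal(mesh_area(sq_k), k^2 * mesh_area(sq))
  # duplicate faces (opposite winding) are counted once
  dup <- triangle_mesh(sq$vertices, rbind(c(1, 2, 3), c(3, 2, 1), c(1, 3, 4)))
  expect_equal(mesh_area(dup), 1.0)
  # invalid faces rejected
  expect_error(triangle_mesh(sq$vertices, rbind(c(1, 2, 9))), "range")
  expect_error(triangle_mesh(sq$vertices, rbind(c(1, 1, 2))), "twice")
})

test_that("mesh_area agrees with the Heron oracle to 1e-12 relative", {
  fx <- generate_leaf("half-cylinder", density = 6e4, seed = 3)
  mesh <- bpa_reconstruct(fx$cloud)
  a1 <- mesh_area(mesh)
  a2 <- heron_mesh_area(mesh)
  expect_lt(abs(a1 - a2) / a1, 1e-12)
})

test_that("ball pivoting meshes a regular grid to within 3% of its area", {
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 50),
                             y = seq(0, 1, length.out = 50)))
  mesh <- bpa_reconstruct(point_cloud(cbind(g, 0)),
                          bpa_params(c(1.5, 2.5) / 49))
  expect_lt(abs(mesh_area(mesh) - 1.0), 0.03)
  # vertices are a subset of the input
  expect_equal(mesh$vertices, cbind(g, 0), ignore_attr = TRUE)
})

test_that("ball pivoting handles minimal inputs", {
  tri <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  mesh <- bpa_reconstruct(tri, bpa_params(2))
  expect_equal(nrow(mesh$faces), 1L)
  expect_equal(mesh_area(mesh), 0.5)
  expect_error(bpa_reconstruct(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))),
               "at least 3")
  # no triangle reachable at a tiny radius
  expect_error(bpa_reconstruct(tri, bpa_params(1e-6)), "radius|radii")
  expect_error(bpa_params(c(2, 1)), "ascending")
})

test_that("leaf pipeline recovers analytic areas within 5%", {
  fx <- generate_leaf("half-cylinder", density = 1.1e5, seed = 1)
  res <- leaf_area_pipeline(fx$cloud)
  expect_lt(abs(res$area_m2 - fx$truth$leaf_area) / fx$truth$leaf_area,
            0.05)
  expect_equal(res$area_cm2, res$area_m2 * 1e4)
  expect_gt(res$diagnostics$vertex_usage, 0.95)
  fd <- generate_leaf("flat-disc", seed = 2)
  resd <- leaf_area_pipeline(fd$cloud)
  expect_lt(abs(resd$area_m2 - pi * 0.0025) / (pi * 0.0025), 0.05)
  expect_error(leaf_area_pipeline(point_cloud(is_metric = TRUE)), "empty")
})

test_that("leaf area is invariant under rigid motion of the cloud", {
  fx <- generate_leaf("flat-disc", density = 8e4, seed = 9)
  base <- leaf_area_pipeline(fx$cloud)$area_m2
  R <- seeded_rotation(10)
  moved <- rigid_motion(fx$cloud, R, c(1, -2, 0.5))
  attr(moved, "is_metric") <- TRUE
  expect_equal(leaf_area_pipeline(moved)$area_m2, base, tolerance = 1e-9)
})

test_that("non-metric leaf clouds are refused", {
  pc <- point_cloud(matrix(runif(300), 100, 3))
  expect_error(leaf_area_pipeline(pc), "metric")
})
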