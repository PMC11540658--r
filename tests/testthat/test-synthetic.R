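test_that("fixtures regenerate bit-for-bit under the same seed", {
  a <- generate_stem(seed = 5, density = 2e4, min_organ_points = 200)
  b <- generate_stem(seed = 5, density = 2e4, min_organ_points = 200)
  expect_identical(cbind(a$cloud$x, a$cloud$y, a$cloud$z),
                   cbind(b$cloud$x, b$cloud$y, b$cloud$z))
  # byte-identical PLY output
  f1 <- tempfile(fileext = ".ply"); f2 <- tempfile(fileext = ".ply")
  write_fixture(a, dirname(f1), tools::file_path_sans_ext(basename(f1)))
  write_fixture(b, dirname(f2), tools::file_path_sans_ext(basename(f2)))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the cloud
  c_ <- generate_fruit(seed = 6)
  d_ <- generate_fruit(seed = 7)
  expect_false(identical(c_$cloud$x, d_$cloud$x))
})

test_that("stem truth is analytic: spacings and node positions", {
  fx <- generate_stem(node_spacings = c(0.25), density = 2e4,
                      min_organ_points = 200, seed = 1)
  expect_equal(fx$truth$inter_node_distances, 0.25)
  expect_equal(nrow(fx$truth$node_positions), 2L)
  expect_equal(diff(fx$truth$node_positions[, 3]), 0.25)
  expect_true(is_metric(fx$cloud))
  expect_error(generate_stem(node_spacings = c(-1)), "> 0")
})

test_that("leaf truth areas are closed-form", {
  fd <- generate_leaf("flat-disc", disc_radius = 0.05, seed = 1)
  expect_equal(fd$truth$leaf_area, pi * 0.0025)
  fh <- generate_leaf("half-cylinder", cyl_radius = 0.05,
                      cyl_height = 0.12, seed = 1)
  expect_equal(fh$truth$leaf_area, pi * 0.05 * 0.12)
  expect_error(generate_leaf("s-curl", curl_angle = 4), "domain")
})

test_that("s-curl truth area matches numeric quadrature to 1e-6 relative", {
  fs <- generate_leaf("s-curl", curl_radius = 0.03, curl_angle = 2.0,
                      curl_width = 0.08, seed = 1)
  q <- s_curl_area_quadrature(0.03, 2.0, 0.08)
  expect_lt(abs(fs$truth$leaf_area - q) / q, 1e-6)
})

test_that("fruit coverage cut retains only view-facing normals", {
  ax <- c(0.04, 0.03, 0.03)
  fx <- generate_fruit(ax, coverage = 0.5, view = c(1, 0, 0),
                       n_points = 1200, noise_sd = 0, seed = 3)
  m <- cbind(fx$cloud$x, fx$cloud$y, fx$cloud$z)
  normals <- cbind(m[, 1] / ax[1]^2, m[, 2] / ax[2]^2, m[, 3] / ax[3]^2)
  normals <- normals / sqrt(rowSums(normals^2))
  expect_true(all(normals[, 1] >= -1e-9))
  expect_equal(fx$truth$fruit_volume, 4 / 3 * pi * prod(ax))
  # sphere fixture trivia
  sp <- generate_fruit(c(0.03, 0.03, 0.03), seed = 1)
  expect_equal(sp$truth$fruit_volume, 1.13097e-4, tolerance = 1e-5)
  expect_error(generate_fruit(coverage = 0), "coverage")
})

test_that("full-ellipsoid sampling is area-uniform (dispersion bound)", {
  ax <- c(0.04, 0.03, 0.03)
  fx <- generate_fruit(ax, n_points = 4000, noise_sd = 0, seed = 9)
  m <- cbind(fx$cloud$x, fx$cloud$y, fx$cloud$z)
  # mean nearest-neighbor distance should match the Poisson expectation
  # for the analytic surface area (Thomsen's approximation)
  p <- 1.6075  # Thomsen's surface-area approximation
  area <- 4 * pi * (((ax[1] * ax[2])^p + (ax[1] * ax[3])^p +
                       (ax[2] * ax[3])^p) / 3)^(1 / p)
  expected_nn <- 0.5 / sqrt(4000 / area)
  nn <- RANN::nn2(m, k = 2)$nn.dists[, 2]
  expect_lt(abs(mean(nn) - expected_nn) / expected_nn, 0.1)
  # local density at the sharp end vs the equator stays balanced
  u <- m[, 1] / ax[1]
  tip <- abs(u) > 0.85
  mid <- abs(u) < 0.3
  r10 <- RANN::nn2(m, k = 11)$nn.dists[, 11]
  ratio <- median(r10[tip]) / median(r10[mid])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("marker fixtures invert through estimate_scale", {
  mk <- generate_marker(scale = 5, seed = 1)
  expect_equal(mk$truth$scale_factor, 0.2)
  expect_equal(estimate_scale(mk$observation)$scale_factor, 0.2,
               tolerance = 1e-12)
  expect_equal(estimate_scale(mk$observation)$residual_rms, 0,
               tolerance = 1e-12)
  # noisy corners: recovered scale within 1% across seeds
  recovered <- vapply(1:100, function(s) {
    estimate_scale(generate_marker(scale = 5, corner_noise_sd = 0.001,
                                   seed = s)$observation)$scale_factor
  }, numeric(1))
  expect_true(all(abs(recovered - 0.2) / 0.2 < 0.01))
})

test_that("the standard fixture suite materializes on disk", {
  td <- file.path(tempdir(), "fixture-suite")
  tab <- make_fixture_suite(td, seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_true(all(file.exists(tab$path)))
  expect_true(all(file.exists(file.path(td, paste0(tab$name,
                                                   "_truth.json")))))
  # truth JSON round-trips the analytic values
  tr <- jsonlite::read_json(file.path(td, "leaf_disc_truth.json"))
  expect_equal(tr$truth$leaf_area, pi * 0.0025, tolerance = 1e-12)
})
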