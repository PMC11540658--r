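test_that("scale estimation reduces to edge-length ratios", {
  obs <- marker_observation(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                            physical_edge_length = 0.30)
  cal <- estimate_scale(obs)
  expect_equal(cal$scale_factor, 0.2)
  # corners already metric: scale 1, residual 0
  sq <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.3, 0), c(0, 0.3, 0))
  cal2 <- estimate_scale(marker_observation(sq))
  expect_equal(cal2$scale_factor, 1.0)
  expect_equal(cal2$residual_rms, 0)
})

test_that("a rotated, scaled square marker inverts to its scale factor", {
  sq_m <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.3, 0), c(0, 0.3, 0))
  s <- 0.137  # meters per reconstruction unit
  R <- seeded_rotation(21)
  corners <- (sq_m / s) %*% t(R)
  corners <- sweep(corners, 2, c(3, -1, 2), `+`)
  cal <- estimate_scale(marker_observation(corners))
  expect_equal(cal$scale_factor, s, tolerance = 1e-9)
  expect_lt(cal$residual_rms, 1e-12)
})

test_that("estimate_scale is invariant to rigid motion of the corners", {
  mk <- generate_marker(scale = 4, seed = 31, corner_noise_sd = 0.002)
  base <- estimate_scale(mk$observation)
  R <- seeded_rotation(32)
  moved <- marker_observation(
    sweep(mk$observation$corners %*% t(R), 2, c(5, 5, 5), `+`),
    physical_edge_length = mk$observation$physical_edge_length)
  expect_equal(estimate_scale(moved)$scale_factor, base$scale_factor,
               tolerance = 1e-12)
})

test_that("apply_scale metrifies coordinates and guards double scaling", {
  set.seed(41)
  pc <- point_cloud(matrix(rnorm(60), 20, 3))
  scaled <- apply_scale(pc, 2.0)
  expect_true(is_metric(scaled))
  d0 <- dist(cbind(pc$x, pc$y, pc$z))
  d1 <- dist(cbind(scaled$x, scaled$y, scaled$z))
  expect_equal(as.vector(d1), as.vector(2 * d0))
  expect_error(apply_scale(scaled, 2.0), "already metric")
  # identity scale
  expect_cloud_equal(apply_scale(pc, 1.0), pc)
  # bounding-box diagonal scales exactly
  s02 <- apply_scale(pc, 0.2)
  diag0 <- sqrt(sum((apply(cbind(pc$x, pc$y, pc$z), 2, max) -
                       apply(cbind(pc$x, pc$y, pc$z), 2, min))^2))
  diag1 <- sqrt(sum((apply(cbind(s02$x, s02$y, s02$z), 2, max) -
                       apply(cbind(s02$x, s02$y, s02$z), 2, min))^2))
  expect_equal(diag1, 0.2 * diag0)
})

test_that("apply-then-estimate returns unit scale", {
  mk <- generate_marker(scale = 7, seed = 51)
  cal <- estimate_scale(mk$observation)
  metric_corners <- mk$observation$corners * cal$scale_factor
  cal2 <- estimate_scale(marker_observation(metric_corners))
  expect_equal(cal2$scale_factor, 1.0, tolerance = 1e-12)
})

test_that("degenerate markers are rejected", {
  expect_error(marker_observation(rbind(c(0, 0, 0), c(0, 0, 0))),
               "distinct")
  expect_error(
    marker_observation(rbind(c(0, 0, 0), c(1, 0, 0)),
                       physical_edge_length = -1), "> 0")
})

test_that("calibration JSON persists and reloads", {
  mk <- generate_marker(scale = 5, seed = 61)
  cal <- estimate_scale(mk$observation)
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$scale_factor, cal$scale_factor)
  expect_equal(back$marker_edge_m, 0.30)
})
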