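test_that("exact unit-sphere samples recover (1,1,1) to 1e-6", {
  fx <- generate_fruit(c(1, 1, 1), n_points = 500, noise_sd = 0, seed = 1)
  fit <- fit_ellipsoid(fx$cloud)
  expect_equal(unname(fit$semi_axes), c(1, 1, 1), tolerance = 1e-6)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$volume, 4 * pi / 3, tolerance = 1e-5)
})

test_that("full-coverage exact ellipsoid samples recover the semi-axes", {
  ax <- c(0.040, 0.030, 0.030)
  fx <- generate_fruit(ax, n_points = 800, noise_sd = 0, seed = 2)
  fit <- fit_ellipsoid(fx$cloud)
  expect_equal(unname(fit$semi_axes), ax, tolerance = 1e-4)
  truth_v <- 4 / 3 * pi * prod(ax)
  expect_lt(abs(fit$volume - truth_v) / truth_v, 0.001)
  # independent two-stage grid search lands on the same minimum
  oracle <- ellipsoid_grid_oracle(cbind(fx$cloud$x, fx$cloud$y, fx$cloud$z))
  expect_true(all(abs(fit$semi_axes - oracle$axes) <= oracle$step + 1e-12))
})

test_that("principal-frame alignment recovers pose", {
  ax <- c(0.040, 0.030, 0.022)
  fx <- generate_fruit(ax, n_points = 600, noise_sd = 0, seed = 3)
  al0 <- align_to_principal_frame(fx$cloud)
  # center of finite samples of a centered body: near zero at the
  # sampling-fluctuation scale
  expect_lt(max(abs(al0$center)), 1e-3)
  expect_equal(det(al0$orientation), 1, tolerance = 1e-9)
  # translation equivariance: the estimated center follows exactly
  moved <- rigid_motion(fx$cloud, diag(3), c(1, 2, 3))
  al1 <- align_to_principal_frame(moved)
  expect_equal(al1$center - al0$center, c(1, 2, 3), tolerance = 1e-6)
  # rotated cloud: recovered axes span the same frame (signed permutation)
  R <- seeded_rotation(4)
  rot <- rigid_motion(fx$cloud, R)
  al2 <- align_to_principal_frame(rot)
  # columns of R^T %*% orientation should form a signed permutation
  P <- t(R) %*% al2$orientation
  expect_equal(sort(round(abs(P)[abs(P) > 0.5], 3)), rep(1, 3),
               tolerance = 0.05)
  expect_error(align_to_principal_frame(point_cloud(matrix(1:9, 3, 3))),
               "at least 10")
  flat <- point_cloud(cbind(runif(50), runif(50), 0))
  expect_error(align_to_principal_frame(flat), "degenerate|coplanar")
})

test_that("half-coverage occluded fruit recovers volume within 10%", {
  fx <- generate_fruit(c(0.040, 0.030, 0.030), coverage = 1,
                       n_points = 1500, noise_sd = 5e-4, seed = 11)
  half <- crop_cloud(fx$cloud, crop_region_box(c(0, -1, -1), c(1, 1, 1)))
  res <- fruit_volume_pipeline(half)
  expect_lt(abs(res$fit$volume - fx$truth$fruit_volume) /
              fx$truth$fruit_volume, 0.10)
  expect_lt(res$coverage, 0.9)  # diagnostic sees the missing half
})

test_that("fruit pipeline reports cm^3 and propagates preconditions", {
  fx <- generate_fruit(c(0.03, 0.03, 0.03), n_points = 500, noise_sd = 0,
                       seed = 1)
  res <- fruit_volume_pipeline(fx$cloud)
  expect_equal(res$volume_cm3, 4 / 3 * pi * 27, tolerance = 0.01)
  expect_error(fruit_volume_pipeline(
    point_cloud(matrix(rnorm(15), 5, 3), is_metric = TRUE)), "10")
  expect_error(fruit_volume_pipeline(point_cloud(matrix(rnorm(60), 20, 3))),
               "metric")
})

test_that("reported volume matches Monte-Carlo inside-testing within 1%", {
  fx <- generate_fruit(c(0.035, 0.028, 0.024), n_points = 900,
                       noise_sd = 2e-4, seed = 21)
  fit <- fruit_volume_pipeline(fx$cloud)$fit
  a <- fit$semi_axes
  set.seed(22)
  n_mc <- 1e5
  u <- cbind(runif(n_mc, -a[1], a[1]), runif(n_mc, -a[2], a[2]),
             runif(n_mc, -a[3], a[3]))
  inside <- rowSums(sweep(u, 2, a, `/`)^2) <= 1
  v_mc <- mean(inside) * 8 * prod(a)
  expect_lt(abs(v_mc - fit$volume) / fit$volume, 0.01)
})

test_that("volume is invariant under rigid motion", {
  fx <- generate_fruit(c(0.040, 0.030, 0.030), coverage = 0.8,
                       n_points = 1000, seed = 31)
  base <- fruit_volume_pipeline(fx$cloud)$fit$volume
  R <- seeded_rotation(32)
  moved <- rigid_motion(fx$cloud, R, c(0.4, 0.1, -1.0))
  attr(moved, "is_metric") <- TRUE
  expect_equal(fruit_volume_pipeline(moved)$fit$volume, base,
               tolerance = 1e-6)
})

test_that("ellipsoid_fit invariants and broom methods hold", {
  fx <- generate_fruit(c(0.04, 0.03, 0.03), n_points = 500, seed = 41)
  fit <- fruit_volume_pipeline(fx$cloud)$fit
  expect_true(all(fit$semi_axes > 0))
  expect_gte(fit$residual, 0)
  expect_equal(fit$volume, 4 / 3 * pi * prod(fit$semi_axes))
  o <- fit$orientation
  expect_equal(t(o) %*% o, diag(3), tolerance = 1e-9)
  expect_equal(det(o), 1, tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(td$estimate_mm, td$estimate * 1e3)
  gl <- glance(fit)
  expect_equal(gl$volume_cm3, gl$volume_m3 * 1e6)
  mesh <- ellipsoid_mesh(fit)
  expect_gt(mesh_area(mesh), 0)
})
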