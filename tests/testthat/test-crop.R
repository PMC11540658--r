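test_that("box crop keeps exactly the inside points, inclusively", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(2, 2, 2), c(1, 1, 1)))
  box <- crop_region_box(c(0, 0, 0), c(1, 1, 1))
  out <- crop_cloud(pc, box)
  expect_equal(n_points(out), 2L)  # bounds are inclusive
  # full bounding box is the identity
  all_box <- crop_region_box(c(0, 0, 0), c(2, 2, 2))
  expect_cloud_equal(crop_cloud(pc, all_box), pc)
  # empty result is valid
  far <- crop_region_box(c(10, 10, 10), c(11, 11, 11))
  expect_equal(n_points(crop_cloud(pc, far)), 0L)
})

test_that("polygon crop matches the per-point ray-casting oracle", {
  set.seed(11)
  pc <- point_cloud(cbind(runif(100), runif(100), runif(100)))
  tri <- rbind(c(0.1, 0.1), c(0.9, 0.2), c(0.4, 0.9))
  region <- crop_region_polygon(tri, view = c(0, 0, 1))
  out <- crop_cloud(pc, region)
  # oracle on the projected (x, y) coordinates; +z view projects to a
  # plane whose basis here is (x, y) up to orientation
  uv <- phenocloud:::project_to_view_plane(cbind(pc$x, pc$y, pc$z),
                                           c(0, 0, 1))
  expected <- vapply(seq_len(100), function(i) {
    point_in_polygon_oracle(uv[i, 1], uv[i, 2], tri)
  }, logical(1))
  # oracle selects in the same projected frame the crop uses
  expect_equal(n_points(out), sum(expected))
  expect_equal(cbind(out$x, out$y, out$z),
               cbind(pc$x, pc$y, pc$z)[expected, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("crop is idempotent and returns a subset in input order", {
  set.seed(12)
  pc <- point_cloud(matrix(runif(300), 100, 3),
                    colors = matrix(runif(300), 100, 3))
  regions <- list(
    crop_region_box(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8)),
    crop_region_polygon(rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.5, 0.9)),
                        view = c(1, 1, 1))
  )
  for (r in regions) {
    once <- crop_cloud(pc, r)
    twice <- crop_cloud(once, r)
    expect_cloud_equal(once, twice)
    # subset property: every output row occurs in the input
    key_in <- paste(pc$x, pc$y, pc$z)
    key_out <- paste(once$x, once$y, once$z)
    expect_true(all(key_out %in% key_in))
    # order preserved and colors carried
    expect_equal(match(key_out, key_in), sort(match(key_out, key_in)))
    expect_true(has_colors(once))
  }
})

test_that("invalid regions are rejected", {
  expect_error(crop_region_box(c(1, 0, 0), c(0, 1, 1)), "min")
  expect_error(crop_region_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
  expect_error(crop_region_polygon(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                   view = c(0, 0, 0)), "nonzero")
})
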