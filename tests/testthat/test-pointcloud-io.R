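test_that("PLY and XYZ round-trips are lossless, including colors", {
  set.seed(101)
  m <- matrix(rnorm(30), 10, 3)
  cols <- matrix(runif(30), 10, 3)
  pc <- point_cloud(m, colors = cols)
  for (fmt in c("ply", "xyz")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pc, f)
    back <- read_point_cloud(f)
    expect_cloud_equal(pc, back)
    expect_equal(cbind(back$red, back$green, back$blue), cols,
                 ignore_attr = TRUE)
  }
  # ASCII PLY dialect round-trips too
  f <- tempfile(fileext = ".ply")
  write_point_cloud(pc, f, binary = FALSE)
  expect_cloud_equal(pc, read_point_cloud(f))
})

test_that("a 10,000-point binary PLY round-trip preserves every coordinate", {
  set.seed(7)
  pc <- point_cloud(matrix(rnorm(30000), 10000, 3))
  f <- tempfile(fileext = ".ply")
  write_point_cloud(pc, f)
  back <- read_point_cloud(f)
  expect_identical(cbind(back$x, back$y, back$z), cbind(pc$x, pc$y, pc$z))
})

test_that("empty clouds are written and read without error", {
  pc <- point_cloud()
  for (fmt in c("ply", "xyz")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pc, f)
    back <- read_point_cloud(f)
    expect_equal(n_points(back), 0L)
  }
  # hand-written 0-vertex ASCII PLY
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 0",
               "property double x", "property double y",
               "property double z", "end_header"), f)
  expect_equal(n_points(read_point_cloud(f)), 0L)
})

test_that("malformed inputs raise informative parse errors", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 2", "3 3 3"), f)
  expect_error(read_point_cloud(f), "row 2")
  writeLines(c("0 0 0", "1 x 2"), f)
  expect_error(read_point_cloud(f), "non-numeric")
  g <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property double x", "property double y",
               "property double z", "end_header", "1 bad 3"), g)
  expect_error(read_point_cloud(g), "non-numeric")
  expect_error(read_point_cloud(tempfile(fileext = ".ply")), "not found")
})

test_that("metric status survives the sidecar round-trip", {
  pc <- apply_scale(point_cloud(matrix(rnorm(30), 10, 3)), 0.5)
  f <- tempfile(fileext = ".ply")
  write_point_cloud(pc, f)
  expect_true(is_metric(read_point_cloud(f)))
  # and without a sidecar the cloud is non-metric
  file.remove(paste0(f, ".json"))
  expect_false(is_metric(read_point_cloud(f)))
})

test_that("point cloud construction validates its inputs", {
  expect_error(point_cloud(matrix(c(1, 2), 1, 2)), "3 columns")
  expect_error(point_cloud(matrix(c(1, NA, 3), 1, 3)), "finite")
  expect_error(point_cloud(matrix(1, 2, 3), colors = matrix(1, 1, 3)),
               "rows")
  expect_error(point_cloud(matrix(1, 1, 3), colors = matrix(2, 1, 3)),
               "\\[0, 1\\]")
})
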