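# shared geometric helpers and independent oracles

rigid_motion <- function(cloud, R, t = c(0, 0, 0)) {
  m <- cbind(cloud$x, cloud$y, cloud$z) %*% t(R)
  m <- sweep(m, 2, t, `+`)
  out <- cloud
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  out
}

seeded_rotation <- function(seed) {
  withr::with_seed(seed, random_rotation())
}

# independent per-point ray-casting containment oracle (scalar loop,
# deliberately naive)
point_in_polygon_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Heron's-formula mesh area (independent of the cross-product route)
heron_mesh_area <- function(mesh) {
  f <- mesh$faces
  key <- t(apply(f, 1, sort))
  f <- f[!duplicated(key), , drop = FALSE]
  v <- mesh$vertices
  total <- 0
  for (i in seq_len(nrow(f))) {
    a <- sqrt(sum((v[f[i, 1], ] - v[f[i, 2], ])^2))
    b <- sqrt(sum((v[f[i, 2], ] - v[f[i, 3], ])^2))
    c_ <- sqrt(sum((v[f[i, 3], ] - v[f[i, 1], ])^2))
    s <- (a + b + c_) / 2
    h2 <- s * (s - a) * (s - b) * (s - c_)
    total <- total + sqrt(max(h2, 0))
  }
  total
}

# exhaustive minimum spanning tree weight via Prufer-sequence
# enumeration of all n^(n-2) labeled trees
brute_force_mst_weight <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 3, n <= 8)
  d <- as.matrix(dist(coords))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (row in seq_len(nrow(seqs))) {
    prufer <- seqs[row, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    w <- 0
    deg <- degree
    for (v in prufer) {
      leaf <- which(deg == 1L)[1]
      w <- w + d[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    last <- which(deg == 1L)
    w <- w + d[last[1], last[2]]
    if (w < best) best <- w
  }
  best
}

# two-stage exhaustive grid search over (a, b, c) for the algebraic
# ellipsoid objective; vectorized through the moment matrices
ellipsoid_grid_oracle <- function(m, steps = 40) {
  sq <- m^2
  A <- crossprod(sq)
  b <- colSums(sq)
  n <- nrow(m)
  eval_grid <- function(lo, hi) {
    ax <- lapply(1:3, function(j) seq(lo[j], hi[j], length.out = steps))
    g <- as.matrix(expand.grid(ax))
    Q <- 1 / g^2
    f <- rowSums((Q %*% A) * Q) - 2 * drop(Q %*% b) + n
    best <- which.min(f)
    list(axes = g[best, ], step = (hi - lo) / (steps - 1))
  }
  init <- apply(abs(m), 2, max)
  s1 <- eval_grid(0.25 * init, 2 * init)
  lo <- pmax(s1$axes - 2 * s1$step, 1e-9)
  s2 <- eval_grid(lo, s1$axes + 2 * s1$step)
  s2
}

# numeric surface-area quadrature for the s-curl sheet: arc length of
# the generating curve by finite differences times the width
s_curl_area_quadrature <- function(R, psi, width, n = 200000) {
  t <- seq(0, 2 * R * psi, length.out = n)
  cv <- phenocloud:::s_curl_curve(t, R, psi)
  arc <- sum(sqrt(diff(cv$x)^2 + diff(cv$z)^2))
  arc * width
}

expect_cloud_equal <- function(a, b, tol = 0) {
  expect_equal(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z), tolerance = tol)
}
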