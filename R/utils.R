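`%||%` <- function(x, y) if (is.null(x)) y else x

# unit-quaternion -> rotation matrix; used for seeded random rotations
quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Draw a uniformly distributed random rotation matrix
#'
#' Samples a unit quaternion from the isotropic distribution (four iid
#' normals, normalized) and converts it to a proper rotation matrix.
#' Useful for rigid-motion invariance checks and for posing synthetic
#' fixtures.
#'
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  quat_to_rotation(stats::rnorm(4))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

# median nearest-neighbor spacing; the density scale most parameter
# defaults hang off
median_nn_distance <- function(m) {
  if (nrow(m) < 2) return(NA_real_)
  nn <- RANN::nn2(m, k = 2)
  stats::median(nn$nn.dists[, 2])
}

# principal axes of a point set with a deterministic, intrinsic sign
# convention: each of the first two axes is oriented by the skewness of
# the projected distribution (a property of the data, not of the world
# frame, so canonical coordinates are identical for rigidly moved
# inputs); near-symmetric distributions fall back to the
# largest-|component| rule. Third axis by cross product
# (right-handedness).
principal_frame <- function(m) {
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  cv <- crossprod(cm) / max(1, nrow(m) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ax <- eg$vectors  # columns, descending eigenvalue
  for (j in 1:2) {
    t <- drop(cm %*% ax[, j])
    sk <- mean(t^3)
    sd3 <- (sqrt(mean(t^2)) + 1e-300)^3
    if (abs(sk) > 1e-4 * sd3) {
      if (sk < 0) ax[, j] <- -ax[, j]
    } else {
      k <- which.max(abs(ax[, j]))
      if (ax[k, j] < 0) ax[, j] <- -ax[, j]
    }
  }
  ax[, 3] <- cross3(ax[, 1], ax[, 2])
  list(center = unname(ctr), axes = unname(ax),
       sdev = sqrt(pmax(eg$values, 0)))
}

# voxel-grid downsampling in an arbitrary frame; returns voxel centroids.
# Binning in a canonical (PCA) frame keeps the result equivariant under
# rigid motion of the input.
voxel_downsample <- function(m, spacing, frame = NULL) {
  stopifnot(spacing > 0)
  if (nrow(m) == 0) return(m)
  local <- if (is.null(frame)) m else sweep(m, 2, frame$center) %*% frame$axes
  key <- floor(sweep(local, 2, spacing, `/`))
  id <- paste(key[, 1], key[, 2], key[, 3], sep = "_")
  groups <- split(seq_len(nrow(m)), id)
  out <- t(vapply(groups, function(ix) colMeans(m[ix, , drop = FALSE]),
                  numeric(3)))
  # deterministic order: by voxel key along the canonical axes
  keys <- do.call(rbind, strsplit(names(groups), "_"))
  ord <- order(as.numeric(keys[, 1]), as.numeric(keys[, 2]),
               as.numeric(keys[, 3]))
  out <- out[ord, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# R^2 (1 - SS_res/SS_tot about the truth mean) and squared Pearson
r_squared <- function(predicted, truth) {
  ss_res <- sum((predicted - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  1 - ss_res / ss_tot
}
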