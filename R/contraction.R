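#' Parameters for Laplacian-based contraction
#'
#' Controls the iterative contraction that collapses a point cloud onto
#' its curve skeleton. Each iteration solves, per coordinate, the
#' regularized sparse system that balances a Laplacian smoothness term
#' (weight amplified each iteration) against per-point attraction to the
#' current positions, on a k-nearest-neighbor graph Laplacian with
#' inverse-distance weights. Attraction weights grow as local extent
#' shrinks, anchoring already-collapsed regions.
#'
#' @param k_neighbors neighborhood size for the graph Laplacian (>= 4).
#' @param initial_contraction_weight,initial_attraction_weight positive
#'   starting weights of the two energy terms.
#' @param contraction_amplification factor (> 1, <= 10) applied to the
#'   contraction weight each iteration.
#' @param max_contraction_weight cap on the amplified contraction weight.
#' @param max_iterations iteration cap.
#' @param convergence_ratio stop when the mean local extent (mean
#'   distance to the k nearest neighbors) falls below this fraction of
#'   its original value; contraction also stops when the extent
#'   reduction stalls (under 2 percent relative improvement).
#' @return A `contraction_params` list.
#' @export
contraction_params <- function(k_neighbors = 12,
                               initial_contraction_weight = 1.0,
                               initial_attraction_weight = 1.0,
                               contraction_amplification = 3.0,
                               max_contraction_weight = 2048,
                               max_iterations = 20,
                               convergence_ratio = 0.01) {
  if (k_neighbors < 4) stop("k_neighbors must be >= 4")
  if (initial_contraction_weight <= 0 || initial_attraction_weight <= 0) {
    stop("weights must be > 0")
  }
  if (contraction_amplification <= 1 || contraction_amplification > 10) {
    stop("contraction_amplification must be in (1, 10]")
  }
  if (convergence_ratio <= 0 || convergence_ratio >= 1) {
    stop("convergence_ratio must be in (0, 1)")
  }
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(
    list(k_neighbors = as.integer(k_neighbors),
         initial_contraction_weight = initial_contraction_weight,
         initial_attraction_weight = initial_attraction_weight,
         contraction_amplification = contraction_amplification,
         max_contraction_weight = max_contraction_weight,
         max_iterations = as.integer(max_iterations),
         convergence_ratio = convergence_ratio),
    class = "contraction_params"
  )
}

# mean distance to the k nearest neighbors of each point
local_extent <- function(m, k) {
  k_eff <- min(k, nrow(m) - 1L)
  nn <- RANN::nn2(m, k = k_eff + 1L)
  rowMeans(nn$nn.dists[, -1, drop = FALSE])
}

# row-normalized inverse-distance graph Laplacian on the symmetrized
# kNN graph of `m`. The topology and weights come from the original
# cloud and stay fixed across contraction iterations: recomputing
# neighborhoods on contracted positions lets local clusters become
# self-neighboring, which zeroes the Laplacian force and freezes the
# contraction ("clumping").
knn_laplacian <- function(m, k) {
  n <- nrow(m)
  nn <- RANN::nn2(m, k = min(k + 1L, n))
  i <- rep(seq_len(n), each = ncol(nn$nn.idx) - 1L)
  j <- as.vector(t(nn$nn.idx[, -1, drop = FALSE]))
  d <- as.vector(t(nn$nn.dists[, -1, drop = FALSE]))
  # symmetrize (union of directed kNN edges), keep one weight per pair
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]; d <- d[keep]
  w <- 1 / pmax(d, 1e-9)
  W <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(n, n))
  rs <- Matrix::rowSums(W)
  if (any(rs == 0)) stop("isolated point in neighborhood graph")
  Matrix::Diagonal(n, 1 / rs) %*% W - Matrix::Diagonal(n)
}

#' Contract a point cloud toward its curve skeleton
#'
#' Iterative Laplacian-based contraction: the substrate for stem
#' skeletonization. Point count and order are preserved; contracted
#' positions replace the originals.
#'
#' @param cloud a [point_cloud()] with at least `k_neighbors + 1`
#'   points, not all coincident.
#' @param params a [contraction_params()].
#' @return The contracted `point_cloud`, with attribute `iterations`
#'   (iterations run) and `extent_ratio` (final mean local extent /
#'   original).
#' @export
contract_point_cloud <- function(cloud, params = contraction_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!inherits(params, "contraction_params")) {
    stop("`params` must come from contraction_params()")
  }
  p <- pc_matrix(cloud)
  n <- nrow(p)
  if (n < params$k_neighbors + 1L) {
    stop("too few points for contraction: ", n, " < k_neighbors + 1 = ",
         params$k_neighbors + 1L)
  }
  spread <- max(apply(p, 2, function(v) diff(range(v))))
  if (spread < 1e-12) stop("degenerate geometry: all points coincident")

  s0 <- local_extent(p, params$k_neighbors)
  s0 <- pmax(s0, 1e-12)
  wl <- params$initial_contraction_weight
  wh0 <- params$initial_attraction_weight
  mean_s0 <- mean(s0)
  prev_mean <- mean_s0
  x <- p
  iters <- 0L
  L <- knn_laplacian(p, params$k_neighbors)
  for (it in seq_len(params$max_iterations)) {
    s <- pmax(local_extent(x, params$k_neighbors), 1e-12)
    wh <- wh0 * s0 / s
    lhs <- wl^2 * Matrix::crossprod(L) + Matrix::Diagonal(n, wh^2)
    rhs <- wh^2 * x
    x_new <- tryCatch(
      as.matrix(Matrix::solve(lhs, rhs)),
      error = function(e) {
        stop("contraction linear system failed (degenerate geometry?): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (any(!is.finite(x_new))) {
      stop("contraction produced non-finite coordinates (degenerate geometry)")
    }
    x <- x_new
    iters <- it
    mean_s <- mean(local_extent(x, params$k_neighbors))
    if (mean_s < params$convergence_ratio * mean_s0) break
    if (it > 1 && mean_s > prev_mean * 0.95) break  # stalled
    prev_mean <- mean_s
    wl <- min(wl * params$contraction_amplification,
              params$max_contraction_weight)
  }
  out <- pc_replace_coords(cloud, x)
  attr(out, "iterations") <- iters
  attr(out, "extent_ratio") <- mean(local_extent(x, params$k_neighbors)) / mean_s0
  out
}
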