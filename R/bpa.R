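#' Parameters for ball-pivoting surface reconstruction
#'
#' @param radii strictly ascending ball radii in meters; `NULL`
#'   (default) derives `c(2, 3, 4)` times the median nearest-neighbor
#'   distance of the input cloud — a multi-pass schedule in which each
#'   larger ball bridges gaps the smaller ones left open. (Poisson-like
#'   random sampling leaves gaps several times the median spacing;
#'   schedules starting at 1.5x leave pinholes that bias area low.)
#' @return A `bpa_params` list.
#' @export
bpa_params <- function(radii = NULL) {
  if (!is.null(radii)) {
    radii <- as.numeric(radii)
    if (length(radii) < 1 || any(radii <= 0)) stop("radii must be > 0")
    if (is.unsorted(radii, strictly = TRUE)) {
      stop("radii must be strictly ascending")
    }
  }
  structure(list(radii = radii), class = "bpa_params")
}

# PCA normals on k nearest neighbors, oriented consistently by
# propagation along a Euclidean MST (open surfaces have no global
# inside/outside; only consistency matters)
estimate_normals <- function(m, k = 10) {
  n <- nrow(m)
  k_eff <- min(k + 1L, n)
  nn <- RANN::nn2(m, k = k_eff)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- m[nn$nn.idx[i, ], , drop = FALSE]
    q <- sweep(nb, 2, colMeans(nb))
    ev <- eigen(crossprod(q), symmetric = TRUE)
    normals[i, ] <- ev$vectors[, 3]
  }
  if (n < 2) return(normals)
  # MST over kNN graph weighted by normal disagreement, then BFS flips
  i_idx <- rep(seq_len(n), times = k_eff - 1L)
  j_idx <- as.vector(nn$nn.idx[, -1])
  lo <- pmin(i_idx, j_idx); hi <- pmax(i_idx, j_idx)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  w <- 1 - abs(rowSums(normals[lo, , drop = FALSE] * normals[hi, , drop = FALSE]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  tree <- igraph::mst(g, weights = w)
  bfs <- igraph::bfs(tree, root = 1, unreachable = TRUE, father = TRUE)
  ord <- as.integer(bfs$order)
  father <- as.integer(bfs$father)
  for (v in ord) {
    f <- father[v]
    if (!is.na(f) && sum(normals[v, ] * normals[f, ]) < 0) {
      normals[v, ] <- -normals[v, ]
    }
  }
  normals
}

# circumcenter of triangle (pa, pb, pc) via the in-plane 2x2 system;
# returns NULL when collinear
tri_circumcenter <- function(pa, pb, pc) {
  u <- pb - pa; v <- pc - pa
  d11 <- sum(u * u); d22 <- sum(v * v); d12 <- sum(u * v)
  den <- d11 * d22 - d12 * d12
  if (den <= 1e-30 * d11 * d22 || den == 0) return(NULL)
  alpha <- (d22 * (d11 - d12)) / (2 * den)
  beta <- (d11 * (d22 - d12)) / (2 * den)
  pa + alpha * u + beta * v
}

# center of the radius-r ball touching the triangle's three vertices on
# side `s` (+1/-1 relative to the (a,b,c)-order normal); NULL if none
tri_ball_center <- function(pa, pb, pc, r, s) {
  cc <- tri_circumcenter(pa, pb, pc)
  if (is.null(cc)) return(NULL)
  h2 <- r * r - sum((cc - pa)^2)
  if (h2 < 0) return(NULL)
  nrm <- cross3(pb - pa, pc - pa)
  nn <- sqrt(sum(nrm^2))
  if (nn == 0) return(NULL)
  cc + s * sqrt(h2) * (nrm / nn)
}

#' Reconstruct a triangle mesh by ball pivoting
#'
#' A ball of each radius (ascending) rolls over the cloud: it settles on
#' three points to seed a triangle, then pivots around each front edge,
#' emitting a triangle whenever it comes to rest on a third point with
#' no other point inside. Larger radii re-start from the boundary edges
#' the smaller radius left, bridging sampling gaps. Vertex normals are
#' estimated internally (neighborhood PCA, consistently oriented by MST
#' propagation) to keep triangle orientation coherent on the open
#' surfaces that leaves are. Mesh vertices are a subset of input points.
#'
#' @param cloud a [point_cloud()] with at least 3 points.
#' @param params a [bpa_params()].
#' @return A [triangle_mesh()], with attribute `vertex_used` (logical
#'   per input point: participates in at least one face).
#' @export
bpa_reconstruct <- function(cloud, params = bpa_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  m_world <- pc_matrix(cloud)
  n <- nrow(m_world)
  if (n < 3) stop("ball pivoting needs at least 3 points, got ", n)
  # pivoting runs in the cloud's canonical principal frame so that the
  # emitted connectivity (and hence the area) is equivariant under
  # rigid motion of the input; faces index the original points
  m <- if (n >= 4) {
    fr <- principal_frame(m_world)
    sweep(m_world, 2, fr$center) %*% fr$axes
  } else {
    m_world
  }
  radii <- params$radii
  if (is.null(radii)) {
    mnn <- median_nn_distance(m)
    radii <- c(2, 3, 4) * mnn
  }
  normals <- estimate_normals(m, k = min(10L, n - 1L))

  r_max <- max(radii)
  k_cap <- min(n, 120L)
  nbr <- RANN::nn2(m, k = k_cap, searchtype = "radius", radius = 2 * r_max)
  nbr_idx <- nbr$nn.idx  # 0-padded

  edge_count <- new.env(hash = TRUE, parent = emptyenv())
  tri_seen <- new.env(hash = TRUE, parent = emptyenv())
  faces <- vector("list", 2048L)
  nf <- 0L
  used <- logical(n)
  front <- vector("list", 4096L)
  nfr <- 0L
  boundary <- list()

  # numeric keys: vertices fit in (n+1)-ary digits, below 2^53
  base <- n + 1
  ekey <- function(a, b) {
    as.character(if (a < b) a * base + b else b * base + a)
  }
  tkey <- function(a, b, k) {
    lo <- min(a, b, k); hi <- max(a, b, k)
    as.character((a + b + k - lo - hi) * base * base + lo * base + hi)
  }
  ecount <- function(a, b) {
    v <- edge_count[[ekey(a, b)]]
    if (is.null(v)) 0L else v
  }
  einc <- function(a, b) {
    k <- ekey(a, b)
    v <- edge_count[[k]]
    edge_count[[k]] <- if (is.null(v)) 1L else v + 1L
  }
  push_front <- function(entry) {
    nfr <<- nfr + 1L
    if (nfr > length(front)) length(front) <<- 2L * nfr
    front[[nfr]] <<- entry
  }

  neighbors_of <- function(i) {
    ids <- nbr_idx[i, ]
    ids[ids > 0L]
  }

  ball_empty <- function(c_pos, r, exclude) {
    cand <- neighbors_of(exclude[1])
    cand <- cand[!(cand %in% exclude)]
    if (length(cand) == 0) return(TRUE)
    d2 <- rowSums((m[cand, , drop = FALSE] -
                     matrix(c_pos, length(cand), 3, byrow = TRUE))^2)
    all(d2 >= (r * (1 - 1e-7))^2)
  }

  add_triangle <- function(a, b, k, c_pos) {
    tk <- tkey(a, b, k)
    if (!is.null(tri_seen[[tk]])) return(FALSE)
    tri_seen[[tk]] <- TRUE
    nf <<- nf + 1L
    if (nf > length(faces)) length(faces) <<- 2L * nf
    faces[[nf]] <<- c(a, b, k)
    einc(a, b); einc(b, k); einc(k, a)
    used[c(a, b, k)] <<- TRUE
    # push the triangle's edges as front entries with the ball side sign
    for (e in list(c(a, b, k), c(b, k, a), c(k, a, b))) {
      if (ecount(e[1], e[2]) == 1L) {
        nrm <- cross3(m[e[2], ] - m[e[1], ], m[e[3], ] - m[e[1], ])
        nn2_ <- sqrt(sum(nrm^2))
        s <- if (nn2_ == 0) 1 else sign(sum((c_pos - m[e[1], ]) * nrm / nn2_))
        if (s == 0) s <- 1
        push_front(c(e[1], e[2], e[3], s))
      }
    }
    TRUE
  }

  try_pivot <- function(a, b, opp, s, r) {
    pa <- m[a, ]; pb <- m[b, ]
    mp <- (pa + pb) / 2
    e <- pb - pa
    el2 <- sum(e * e)
    rho2 <- r * r - el2 / 4
    if (rho2 <= 0) return(FALSE)
    c_old <- tri_ball_center(pa, pb, m[opp, ], r, s)
    if (is.null(c_old)) return(FALSE)
    that <- e / sqrt(el2)
    u <- c_old - mp
    u <- u - sum(u * that) * that
    un <- sqrt(sum(u * u))
    if (un == 0) return(FALSE)
    u <- u / un
    v <- cross3(that, u)
    dop <- m[opp, ] - mp
    dop <- dop - sum(dop * that) * that
    ang <- function(w) {
      th <- atan2(sum(w * v), sum(w * u))
      if (th <= 1e-9) th <- th + 2 * pi
      th
    }
    if (ang(dop) < pi) v <- -v  # rotate away from the existing triangle first

    cand <- neighbors_of(a)
    cand <- cand[cand != a & cand != b]
    if (length(cand) == 0) return(FALSE)
    Mc <- m[cand, , drop = FALSE]
    dmp <- sqrt(rowSums((Mc - matrix(mp, length(cand), 3, byrow = TRUE))^2))
    keep <- dmp <= r + sqrt(rho2) + 1e-12
    cand <- cand[keep]
    if (length(cand) == 0) return(FALSE)
    Mc <- Mc[keep, , drop = FALSE]

    # vectorized ball centers for all candidates, both sides of the
    # candidate triangle plane
    V <- sweep(Mc, 2, pa)
    d11 <- el2
    d22 <- rowSums(V^2)
    d12 <- drop(V %*% e)
    den <- d11 * d22 - d12^2
    ok <- den > 1e-30 * d11 * pmax(d22, 1e-300)
    if (!any(ok)) return(FALSE)
    alpha <- (d22 * (d11 - d12)) / (2 * den)
    beta <- (d11 * (d22 - d12)) / (2 * den)
    cc <- matrix(pa, length(cand), 3, byrow = TRUE) + alpha *
      matrix(e, length(cand), 3, byrow = TRUE) + beta * V
    h2 <- r * r - rowSums((cc - matrix(pa, length(cand), 3, byrow = TRUE))^2)
    nx <- e[2] * V[, 3] - e[3] * V[, 2]
    ny <- e[3] * V[, 1] - e[1] * V[, 3]
    nz <- e[1] * V[, 2] - e[2] * V[, 1]
    nn_ <- sqrt(nx^2 + ny^2 + nz^2)
    ok <- ok & h2 >= 0 & nn_ > 0
    if (!any(ok)) return(FALSE)
    off <- sqrt(pmax(h2, 0)) / pmax(nn_, 1e-300)
    ks <- c(cand[ok], cand[ok])
    ctr <- rbind(cc[ok, , drop = FALSE] + off[ok] * cbind(nx, ny, nz)[ok, , drop = FALSE],
                 cc[ok, , drop = FALSE] - off[ok] * cbind(nx, ny, nz)[ok, , drop = FALSE])
    w <- ctr - matrix(mp, nrow(ctr), 3, byrow = TRUE)
    th <- atan2(drop(w %*% v), drop(w %*% u))
    th[th <= 1e-9] <- th[th <= 1e-9] + 2 * pi

    navg <- normals[a, ] + normals[b, ]
    for (ix in order(th)) {
      k <- ks[ix]
      ck <- ctr[ix, ]
      if (!is.null(tri_seen[[tkey(a, b, k)]])) next
      if (ecount(a, k) >= 2L || ecount(b, k) >= 2L) next
      if (!ball_empty(ck, r, c(a, b, k))) next
      # coherence with oriented vertex normals: ball sits on the outside
      nk <- navg + normals[k, ]
      if (sum((ck - (pa + pb + m[k, ]) / 3) * nk) < 0) next
      return(add_triangle(b, a, k, ck))
    }
    FALSE
  }

  find_seed <- function(from, r) {
    for (i in from:n) {
      if (used[i]) next
      cand <- neighbors_of(i)
      cand <- cand[cand != i]
      if (length(cand) < 2) next
      d <- sqrt(rowSums((m[cand, , drop = FALSE] -
                           matrix(m[i, ], length(cand), 3, byrow = TRUE))^2))
      keep <- d <= 2 * r
      cand <- cand[keep][order(d[keep])]
      if (length(cand) > 14L) cand <- cand[1:14]
      if (length(cand) < 2) next
      for (ja in seq_along(cand)) {
        for (jb in seq_along(cand)) {
          if (jb <= ja) next
          j <- cand[ja]; k <- cand[jb]
          if (!is.null(tri_seen[[tkey(i, j, k)]])) next
          navg <- normals[i, ] + normals[j, ] + normals[k, ]
          for (s in c(1, -1)) {
            cb <- tri_ball_center(m[i, ], m[j, ], m[k, ], r, s)
            if (is.null(cb)) next
            if (sum((cb - m[i, ]) * navg) < 0) next  # seed on the normal side
            if (!ball_empty(cb, r, c(i, j, k))) next
            a2 <- i; b2 <- j; k2 <- k
            if (sum(cross3(m[b2, ] - m[a2, ], m[k2, ] - m[a2, ]) * navg) < 0) {
              tmp <- b2; b2 <- k2; k2 <- tmp
            }
            if (add_triangle(a2, b2, k2, cb)) return(i)
          }
        }
      }
    }
    0L
  }

  for (r in radii) {
    # boundary edges from the previous radius get another chance
    if (length(boundary) > 0) {
      for (be in boundary) push_front(be)
      boundary <- list()
    }
    seed_ptr <- 1L
    repeat {
      if (nfr > 0L) {
        entry <- front[[nfr]]
        nfr <- nfr - 1L
        a <- entry[1]; b <- entry[2]; opp <- entry[3]; s <- entry[4]
        if (ecount(a, b) != 1L) next
        if (!try_pivot(a, b, opp, s, r)) {
          boundary[[length(boundary) + 1L]] <- entry
        }
      } else {
        hit <- find_seed(seed_ptr, r)
        if (hit == 0L) break
        seed_ptr <- hit
      }
    }
  }

  fmat <- if (nf > 0) do.call(rbind, faces[seq_len(nf)]) else
    matrix(integer(0), ncol = 3)
  if (nf == 0) {
    stop("ball pivoting found no triangle; try larger radii ",
         "(e.g. > ", signif(2 * median_nn_distance(m), 3), ")")
  }
  mesh <- triangle_mesh(m_world, fmat)
  attr(mesh, "vertex_used") <- used
  mesh
}
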