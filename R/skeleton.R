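#' Build a skeleton graph from a contracted point cloud
#'
#' Contracted points are voxel-downsampled at `sample_spacing` to
#' skeleton vertices (binning in the cloud's principal-axis frame, so
#' the result is equivariant under rigid motion), and a minimum spanning
#' tree is computed over the complete Euclidean graph of the vertices
#' (k-nearest-neighbor graph above 5000 vertices, with a connectivity
#' check). Ties between equal-weight edges break lexicographically.
#' Vertex degrees classify branch nodes (degree >= 3) and end nodes
#' (degree 1).
#'
#' @param contracted a contracted [point_cloud()]
#'   (see [contract_point_cloud()]).
#' @param sample_spacing voxel edge length for skeleton vertex
#'   extraction, in the cloud's units (default 5 mm).
#' @param min_twig_length prune terminal twigs (paths from an end node
#'   to the nearest branch vertex) shorter than this; contraction noise
#'   leaves short spurs on the skeleton that would otherwise masquerade
#'   as branch nodes. Default `4 * sample_spacing`; `0` disables.
#' @return A `skeleton_graph`: list with `nodes` (n x 3 matrix), `edges`
#'   (tibble `from`, `to`, `length`), `degree`, `branch_nodes`,
#'   `end_nodes`, `sample_spacing`.
#' @export
build_skeleton_graph <- function(contracted, sample_spacing = 0.005,
                                 min_twig_length = NULL) {
  stopifnot(inherits(contracted, "point_cloud"))
  if (sample_spacing <= 0) stop("sample_spacing must be > 0")
  m <- pc_matrix(contracted)
  if (nrow(m) < 2) stop("need at least 2 points to build a skeleton")
  frame <- if (nrow(m) >= 4) principal_frame(m) else NULL
  v <- voxel_downsample(m, sample_spacing, frame)
  n <- nrow(v)
  if (n < 2) {
    stop("fewer than 2 skeleton vertices after downsampling; ",
         "reduce sample_spacing")
  }
  edges <- if (n <= 5000) {
    complete_edges(v)
  } else {
    knn_edges(v, k = 10)
  }
  mst <- kruskal_mst(n, edges)
  if (nrow(mst) != n - 1) {
    stop("skeleton graph is disconnected; increase neighborhood size ",
         "or sample_spacing")
  }
  min_twig_length <- min_twig_length %||% (4 * sample_spacing)
  if (min_twig_length > 0 && n > 2) {
    pruned <- prune_twigs(v, mst, min_twig_length)
    v <- pruned$nodes
    mst <- pruned$edges
    n <- nrow(v)
  }
  deg <- tabulate(c(mst$from, mst$to), nbins = n)
  structure(
    list(nodes = v,
         edges = tibble::as_tibble(mst),
         degree = deg,
         branch_nodes = which(deg >= 3),
         end_nodes = which(deg == 1),
         sample_spacing = sample_spacing),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "# skeleton_graph: %d vertices, %d edges, %d branch node(s), %d end node(s)\n",
    nrow(x$nodes), nrow(x$edges), length(x$branch_nodes), length(x$end_nodes)))
  invisible(x)
}

complete_edges <- function(v) {
  n <- nrow(v)
  idx <- utils::combn(n, 2)
  d <- sqrt(rowSums((v[idx[1, ], , drop = FALSE] - v[idx[2, ], , drop = FALSE])^2))
  data.frame(from = idx[1, ], to = idx[2, ], length = d)
}

knn_edges <- function(v, k = 10) {
  n <- nrow(v)
  nn <- RANN::nn2(v, k = min(k + 1L, n))
  i <- rep(seq_len(n), times = ncol(nn$nn.idx) - 1L)
  j <- as.vector(nn$nn.idx[, -1])
  d <- as.vector(nn$nn.dists[, -1])
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  data.frame(from = lo[keep], to = hi[keep], length = d[keep])
}

# remove terminal twigs shorter than `threshold` from a tree; vertices
# are re-indexed. A twig runs from an end node to the nearest vertex of
# degree >= 3 (the branch vertex itself is kept). Iterates because
# pruning can expose new short twigs.
prune_twigs <- function(nodes, edges, threshold, max_rounds = 3L) {
  for (round in seq_len(max_rounds)) {
    n <- nrow(nodes)
    deg <- tabulate(c(edges$from, edges$to), nbins = n)
    if (!any(deg >= 3)) break
    adj <- vector("list", n)
    for (e in seq_len(nrow(edges))) {
      f <- edges$from[e]; t <- edges$to[e]
      adj[[f]] <- rbind(adj[[f]], c(t, edges$length[e]))
      adj[[t]] <- rbind(adj[[t]], c(f, edges$length[e]))
    }
    drop <- logical(n)
    for (leaf in which(deg == 1)) {
      path <- leaf
      cum <- 0
      cur <- leaf
      prev <- 0L
      repeat {
        nb <- adj[[cur]]
        nxt <- nb[nb[, 1] != prev, , drop = FALSE]
        if (nrow(nxt) != 1L) break  # reached a branch vertex (or isolated)
        cum <- cum + nxt[1, 2]
        if (cum >= threshold) break
        prev <- cur
        cur <- nxt[1, 1]
        if (deg[cur] >= 3) {
          drop[path] <- TRUE  # twig below threshold: drop it, keep `cur`
          break
        }
        path <- c(path, cur)
      }
    }
    if (!any(drop)) break
    keep <- which(!drop)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    ke <- !drop[edges$from] & !drop[edges$to]
    edges <- edges[ke, , drop = FALSE]
    edges$from <- remap[edges$from]
    edges$to <- remap[edges$to]
    nodes <- nodes[keep, , drop = FALSE]
  }
  list(nodes = nodes, edges = edges)
}

# Kruskal with union-find; edge order (length, from, to) makes equal-weight
# tie-breaking lexicographic and deterministic
kruskal_mst <- function(n, edges) {
  ord <- order(edges$length, edges$from, edges$to)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(n - 1L)
  got <- 0L
  for (e in ord) {
    ra <- find(edges$from[e]); rb <- find(edges$to[e])
    if (ra != rb) {
      parent[ra] <- rb
      got <- got + 1L
      keep[got] <- e
      if (got == n - 1L) break
    }
  }
  edges[keep[seq_len(got)], , drop = FALSE]
}

#' Euclidean distance between two skeleton vertices
#'
#' The inter-node length is the straight-line Euclidean distance between
#' the two vertex coordinates (not the along-tree path length; see
#' [skeleton_path_length()] for that).
#'
#' @param graph a `skeleton_graph`.
#' @param node_a,node_b vertex indices into `graph$nodes`.
#' @return Distance in the graph's units (meters for metric input).
#' @export
inter_node_length <- function(graph, node_a, node_b) {
  stopifnot(inherits(graph, "skeleton_graph"))
  n <- nrow(graph$nodes)
  ids <- c(node_a, node_b)
  if (any(ids < 1 | ids > n | ids != round(ids))) {
    stop("invalid vertex id; graph has ", n, " vertices")
  }
  sqrt(sum((graph$nodes[node_a, ] - graph$nodes[node_b, ])^2))
}

#' Along-tree path length between two skeleton vertices
#'
#' Sum of edge lengths on the unique tree path; reported alongside the
#' straight-line distance for transparency (a curved stem makes the
#' path longer).
#'
#' @inheritParams inter_node_length
#' @return Path length in the graph's units.
#' @export
skeleton_path_length <- function(graph, node_a, node_b) {
  stopifnot(inherits(graph, "skeleton_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
  d <- igraph::distances(g, v = as.character(node_a),
                         to = as.character(node_b),
                         weights = graph$edges$length)
  as.numeric(d[1, 1])
}

#' Candidate measurement nodes of a skeleton
#'
#' Lists branch nodes (degree >= 3) and end nodes (degree 1) with
#' coordinates, sorted by height (z, non-decreasing). Branch nodes
#' closer than `merge_radius` (default twice the sample spacing) are
#' merged to their centroid, since contraction can split one anatomical
#' node across adjacent graph vertices. Selecting which pair of nodes
#' constitutes an inter-node measurement stays with the caller.
#'
#' @param graph a `skeleton_graph`.
#' @param merge_radius merge distance for nearby branch nodes; default
#'   `2 * graph$sample_spacing`.
#' @return Tibble with `id` (representative vertex id; `NA` for merged
#'   centroids of several vertices), `x`, `y`, `z`, `degree`, `kind`
#'   (`"branch"` or `"end"`).
#' @export
extract_node_positions <- function(graph, merge_radius = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  merge_radius <- merge_radius %||% (2 * graph$sample_spacing)
  rows <- list()
  bn <- graph$branch_nodes
  if (length(bn) > 0) {
    bm <- graph$nodes[bn, , drop = FALSE]
    cl <- single_linkage_clusters(bm, merge_radius)
    for (g in unique(cl)) {
      ix <- bn[cl == g]
      ctr <- colMeans(graph$nodes[ix, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = if (length(ix) == 1L) ix else NA_integer_,
        x = ctr[1], y = ctr[2], z = ctr[3],
        degree = max(graph$degree[ix]), kind = "branch")
    }
  }
  for (i in graph$end_nodes) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = i, x = graph$nodes[i, 1], y = graph$nodes[i, 2],
      z = graph$nodes[i, 3], degree = 1L, kind = "end")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                          z = numeric(), degree = integer(),
                          kind = character()))
  }
  dplyr::arrange(out, .data$z)
}

# single-linkage clustering by distance threshold via graph components
single_linkage_clusters <- function(m, radius) {
  n <- nrow(m)
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(m))
  adj <- d <= radius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Export a skeleton graph as ASCII PLY (vertices + edges) and a node CSV
#'
#' @param graph a `skeleton_graph`.
#' @param ply_path output PLY path (edge element carries the tree edges);
#'   `NULL` to skip.
#' @param csv_path output CSV of [extract_node_positions()];
#'   `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_skeleton <- function(graph, ply_path = NULL, csv_path = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (!is.null(ply_path)) {
    con <- file(ply_path, "wb")
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(graph$nodes)),
      "property double x", "property double y", "property double z",
      sprintf("element edge %d", nrow(graph$edges)),
      "property int vertex1", "property int vertex2",
      "end_header",
      apply(graph$nodes, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
      sprintf("%d %d", graph$edges$from - 1L, graph$edges$to - 1L)
    ), con, sep = "\n")
    close(con)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(extract_node_positions(graph), csv_path,
                     row.names = FALSE)
  }
  invisible(c(ply_path, csv_path))
}

#' Measure consecutive inter-node lengths along the main stem
#'
#' Convenience wrapper over the skeleton stage: contracts the cloud,
#' builds the skeleton graph, extracts branch nodes sorted by height and
#' returns the Euclidean distances between consecutive branch nodes —
#' the inter-node lengths of a vertically grown stem.
#'
#' @param cloud a metric stem [point_cloud()].
#' @param params a [contraction_params()].
#' @param sample_spacing skeleton voxel spacing in meters.
#' @return List with `lengths` (numeric vector, meters), `path_lengths`
#'   (along-tree, `NA` for merged nodes), `nodes` (node tibble), and
#'   `graph` (the `skeleton_graph`).
#' @export
stem_internodes <- function(cloud, params = contraction_params(),
                            sample_spacing = 0.005) {
  require_metric(cloud, "inter-node measurement")
  contracted <- contract_point_cloud(cloud, params)
  graph <- build_skeleton_graph(contracted, sample_spacing)
  nodes <- extract_node_positions(graph)
  branch <- nodes[nodes$kind == "branch", , drop = FALSE]
  lens <- numeric(0)
  plens <- numeric(0)
  if (nrow(branch) >= 2) {
    p <- as.matrix(branch[, c("x", "y", "z")])
    lens <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    plens <- vapply(seq_len(nrow(branch) - 1L), function(i) {
      a <- branch$id[i]; b <- branch$id[i + 1L]
      if (is.na(a) || is.na(b)) return(NA_real_)
      skeleton_path_length(graph, a, b)
    }, numeric(1))
  }
  list(lengths = lens, path_lengths = plens, nodes = nodes, graph = graph)
}
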