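# a Y-shaped "already skeletal" cloud: three straight arms from the origin
y_cloud <- function(jitter = 0, seed = 1) {
  dirs <- rbind(c(0, 0, 1), c(1, 0.2, -1) / sqrt(2.04),
                c(-1, -0.2, -1) / sqrt(2.04))
  t <- seq(0.005, 0.3, by = 0.005)
  m <- do.call(rbind, lapply(1:3, function(i) outer(t, dirs[i, ])))
  m <- rbind(c(0, 0, 0), m)
  if (jitter > 0) {
    m <- withr::with_seed(seed, m + matrix(rnorm(length(m), sd = jitter),
                                           nrow(m), 3))
  }
  point_cloud(m)
}

test_that("collinear points give a path graph with total length 3", {
  pc <- point_cloud(cbind(c(0, 1, 2, 3), 0, 0))
  g <- build_skeleton_graph(pc, sample_spacing = 0.5)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sum(g$edges$length), 3)
  expect_equal(sort(g$degree), c(1L, 1L, 2L, 2L))
  nodes <- extract_node_positions(g)
  expect_equal(sum(nodes$kind == "branch"), 0L)
  expect_equal(sum(nodes$kind == "end"), 2L)
})

test_that("the skeleton graph is always a spanning tree", {
  for (seed in c(81, 82)) {
    pc <- point_cloud(withr::with_seed(seed, matrix(runif(450), 150, 3)))
    g <- build_skeleton_graph(pc, sample_spacing = 0.08,
                              min_twig_length = 0)
    n <- nrow(g$nodes)
    expect_equal(nrow(g$edges), n - 1L)
    ig <- igraph::graph_from_data_frame(
      g$edges[, 1:2], directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    expect_true(igraph::is_connected(ig))
    expect_equal(igraph::gsize(ig), n - 1)  # connected + n-1 edges => acyclic
    # every edge weight is the Euclidean distance of its endpoints
    d <- sqrt(rowSums((g$nodes[g$edges$from, , drop = FALSE] -
                         g$nodes[g$edges$to, , drop = FALSE])^2))
    expect_equal(g$edges$length, d)
    expect_true(all(g$edges$length > 0))
  }
})

test_that("MST weight equals the brute-force minimum over all trees", {
  for (n in c(4, 6)) {
    coords <- withr::with_seed(90 + n, matrix(runif(3 * n), n, 3))
    edges <- phenocloud:::complete_edges(coords)
    mst <- phenocloud:::kruskal_mst(n, edges)
    expect_equal(sum(mst$length), brute_force_mst_weight(coords),
                 tolerance = 1e-12)
  }
})

test_that("a Y-shaped skeleton yields one branch node and three ends", {
  g <- build_skeleton_graph(y_cloud(), sample_spacing = 0.01)
  nodes <- extract_node_positions(g)
  expect_equal(sum(nodes$kind == "branch"), 1L)
  expect_equal(sum(nodes$kind == "end"), 3L)
  expect_gte(nodes$degree[nodes$kind == "branch"], 3)
  # node table is sorted by height
  expect_true(!is.unsorted(nodes$z))
})

test_that("inter-node length is the straight-line distance", {
  pc <- point_cloud(cbind(0, 0, c(0, 0.1, 0.25)))
  g <- build_skeleton_graph(pc, sample_spacing = 0.05)
  ends <- g$end_nodes
  top <- ends[which.max(g$nodes[ends, 3])]
  bot <- ends[which.min(g$nodes[ends, 3])]
  expect_equal(inter_node_length(g, bot, top), 0.25)
  expect_equal(inter_node_length(g, top, top), 0)
  expect_error(inter_node_length(g, 0, 1), "invalid")
  # path length along the tree is at least the Euclidean distance
  expect_gte(skeleton_path_length(g, bot, top),
             inter_node_length(g, bot, top) - 1e-12)
})

test_that("skeleton measurements are invariant to rigid motion", {
  pc <- y_cloud(jitter = 2e-4, seed = 5)
  # the full sorted set of branch-to-end distances is frame independent
  measure <- function(cloud) {
    g <- build_skeleton_graph(cloud, sample_spacing = 0.01)
    nodes <- extract_node_positions(g)
    b <- nodes[nodes$kind == "branch", ]
    e <- nodes[nodes$kind == "end", ]
    sort(sqrt((e$x - b$x)^2 + (e$y - b$y)^2 + (e$z - b$z)^2))
  }
  base <- measure(pc)
  R <- seeded_rotation(99)
  moved <- rigid_motion(pc, R, c(0.3, -1.2, 2.5))
  expect_equal(measure(moved), base, tolerance = 1e-9)
})

test_that("stem fixture recovers a planted 0.25 m spacing within 5%", {
  fx <- generate_stem(node_spacings = c(0.25), seed = 17)
  res <- stem_internodes(fx$cloud)
  expect_equal(length(res$lengths), 1L)
  expect_lt(abs(res$lengths - 0.25) / 0.25, 0.05)
})

test_that("skeleton exports are written", {
  g <- build_skeleton_graph(y_cloud(), sample_spacing = 0.01)
  ply <- tempfile(fileext = ".ply")
  csv <- tempfile(fileext = ".csv")
  write_skeleton(g, ply, csv)
  expect_true(file.exists(ply))
  tab <- read.csv(csv)
  expect_true(all(c("x", "y", "z", "degree", "kind") %in% names(tab)))
})
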