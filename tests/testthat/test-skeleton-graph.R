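test_that("MST of collinear points is the path with correct node degrees", {
  P <- cbind(c(0, 1, 2, 3, 4), 0, 0)
  g <- build_mst(P)
  expect_equal(nrow(g$edges), 4)
  expect_equal(sort(g$degree), c(1, 1, 2, 2, 2))
  expect_length(g$endpoints, 2)
  expect_length(g$junctions, 0)
})

test_that("MST weight equals the exhaustive spanning-tree enumeration", {
  sizes <- rep(4:7, length.out = 14)
  for (s in seq_along(sizes)) {
    set.seed(100 + s)
    P <- matrix(runif(3 * sizes[s], 0, 10), ncol = 3)
    g <- build_mst(P)
    expect_equal(sum(g$lengths), min_spanning_weight_exhaustive(P),
                 tolerance = 1e-9)
  }
})

test_that("MST weight is minimal against random spanning-tree samples", {
  set.seed(21)
  P <- matrix(runif(90, 0, 30), ncol = 3)
  g <- build_mst(P)
  n <- nrow(P)
  D <- as.matrix(dist(P))
  w_mst <- sum(g$lengths)
  for (r in 1:1000) {
    seq <- sample.int(n, n - 2, replace = TRUE)
    e <- decode_pruefer(seq, n)
    expect_lte(w_mst, sum(D[e]) + 1e-12)
  }
})

test_that("a three-armed skeleton has exactly one degree-3 junction", {
  g <- build_mst(y_tree_points(c(5, 6, 7)))
  expect_length(g$junctions, 1)
  expect_equal(g$degree[g$junctions], 3)
  expect_length(g$endpoints, 3)
})

test_that("nearby junctions collapse into one vertex at their centroid", {
  # two degree-3 vertices 0.1 mm apart in a 6-leaf tree
  v <- rbind(c(0, 0, 0), c(0.1, 0, 0),             # the two junctions
             c(-5, 5, 0), c(-5, -5, 0),            # arms of junction 1
             c(5.1, 5, 0), c(5.1, -5, 0))          # arms of junction 2
  e <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6))
  len <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  g <- skelreg:::new_skeleton_graph(v, e, len)
  out <- simplify_junctions(g, merge_radius = 5)
  expect_equal(nrow(out$vertices), 5)
  expect_length(out$junctions, 1)
  expect_equal(out$degree[out$junctions], 4)
  expect_equal(out$vertices[out$junctions, ], c(0.05, 0, 0))

  # merge_radius 0 leaves the graph unchanged
  expect_identical(simplify_junctions(g, 0)$vertices, v)

  # a path graph is unchanged for any radius
  p <- build_mst(cbind(0:6, 0, 0))
  expect_identical(simplify_junctions(p, 100)$vertices, p$vertices)
})

test_that("short terminal twigs are pruned, real branches survive", {
  # Y tree with one long arm pair and a 2 mm twig
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(-10, 0, 0), c(0, 2, 0))
  e <- rbind(c(1, 2), c(1, 3), c(1, 4))
  len <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  g <- skelreg:::new_skeleton_graph(v, e, len)
  out <- prune_twigs(g, min_length = 5)
  expect_equal(nrow(out$vertices), 3)
  expect_length(out$junctions, 0)
  # a junction-free path is never pruned
  p <- build_mst(cbind(c(0, 1, 2), 0, 0))
  expect_identical(prune_twigs(p, 100)$vertices, p$vertices)
})

test_that("segment splitting partitions the tree at its nodes", {
  # path graph: one segment containing all vertices in order
  p <- build_mst(cbind(c(0, 1, 2, 3, 4, 5, 6), 0, 0))
  segs <- split_segments(p)
  expect_length(segs, 1)
  expect_equal(length(segs[[1]]$vertices), 7)
  expect_equal(segs[[1]]$kind, "branch")

  # Y tree with arms of 5, 6, 7 vertices: three segments ending at the junction
  g <- build_mst(y_tree_points(c(5, 6, 7)))
  segs <- split_segments(g)
  expect_length(segs, 3)
  sizes <- sort(vapply(segs, function(s) length(s$vertices), integer(1)))
  expect_equal(sizes, c(6, 7, 8))   # arm vertices plus the shared junction
  for (s in segs) {
    expect_equal(s$start_kind, "endpoint")
    expect_equal(s$end_kind, "junction")
    expect_equal(s$kind, "branch")
    expect_gt(s$length, 0)
  }
  # non-node vertices appear exactly once across segments
  all_v <- unlist(lapply(segs, `[[`, "vertices"))
  non_node <- setdiff(all_v, c(g$endpoints, g$junctions))
  expect_equal(anyDuplicated(non_node), 0)
})

test_that("tree paths equal the exhaustive unique-path oracle", {
  for (s in 1:50) {
    set.seed(300 + s)
    n <- sample(4:10, 1)
    P <- matrix(runif(3 * n, 0, 20), ncol = 3)
    edges <- if (n == 2) matrix(c(1, 2), 1) else
      decode_pruefer(sample.int(n, n - 2, replace = TRUE), n)
    len <- sqrt(rowSums((P[edges[, 1], , drop = FALSE] -
                         P[edges[, 2], , drop = FALSE])^2))
    g <- skelreg:::new_skeleton_graph(P, edges, len)
    ig <- skelreg:::graph_as_igraph(g)
    from <- g$endpoints[1]
    to <- g$endpoints[length(g$endpoints)]
    dij <- igraph::shortest_paths(ig, from, to,
                                  weights = igraph::E(ig)$weight)$vpath[[1]]
    oracle <- tree_path_dfs(edges, n, from, to)
    expect_equal(as.integer(dij), oracle)
  }
})
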