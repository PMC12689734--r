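# Fixture generators and small independent oracles shared across test files.
# Everything is built in code; no data files.

# points on a cylinder surface: radius r, axis = z from 0 to len
cylinder_cloud <- function(n, r = 5, len = 100, seed = 1, sigma = 0) {
  set.seed(seed)
  z <- runif(n, 0, len)
  th <- runif(n, 0, 2 * pi)
  P <- cbind(r * cos(th), r * sin(th), z)
  if (sigma > 0) P <- P + matrix(rnorm(3 * n, 0, sigma), n, 3)
  P
}

# a perfect circular ring of m points, radius r, centred at the origin in
# the xy-plane (vessel cross-section; the vessel axis is z)
ring_points <- function(m = 36, r = 5, phase = 0) {
  th <- phase + 2 * pi * (seq_len(m) - 1) / m
  cbind(r * cos(th), r * sin(th), 0)
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_axis_angle(ax, runif(1, 0, pi))
}

# --- exhaustive spanning-tree oracle -----------------------------------------
# decode a Pruefer sequence (values in 1..n, length n-2) into a tree edge list
decode_pruefer <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# minimum total weight over all labelled spanning trees of n points
# (Cayley enumeration via all n^(n-2) Pruefer sequences)
min_spanning_weight_exhaustive <- function(P) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- decode_pruefer(seqs[i, ], n)
    w <- sum(D[e])
    if (w < best) best <- w
  }
  best
}

# unique simple path between two vertices of a tree (DFS), as vertex vector
tree_path_dfs <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  path <- integer(0)
  dfs <- function(v, parent, acc) {
    acc <- c(acc, v)
    if (v == to) return(acc)
    for (w in adj[[v]]) {
      if (w != parent) {
        r <- dfs(w, v, acc)
        if (!is.null(r)) return(r)
      }
    }
    NULL
  }
  dfs(from, 0L, integer(0))
}

# a hand-built Y-shaped skeleton graph: three straight arms meeting at a
# shared junction vertex; arm i has n_i vertices (junction excluded)
y_tree_points <- function(n_arms = c(5, 6, 7), arm_len = 20) {
  dirs <- list(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0))
  pts <- matrix(0, 1, 3)   # junction at origin
  for (a in seq_along(n_arms)) {
    s <- seq_len(n_arms[a]) / n_arms[a] * arm_len
    pts <- rbind(pts, outer(s, unlist(dirs[a])))
  }
  pts
}

# small synthetic feature-curve pair with a known transform between them
feature_pair <- function(seed, max_rot = 40, max_trans = 25) {
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 3, seed = seed))
  curves <- lapply(tree_centerlines(tree), function(P) {
    idx <- round(seq(1, nrow(P), length.out = 20))
    structure(list(samples = P[idx, , drop = FALSE], weight = 1,
                   segment_kind = "trunk"), class = "feature_curve")
  })
  T_gt <- random_rigid_transform(max_rot, max_trans, seed = seed + 1000)
  moved <- lapply(curves, function(cv) {
    cv$samples <- skelreg:::transform_points(cv$samples,
                                             invert_transform(T_gt))
    cv
  })
  list(target = curves, source = moved, T_gt = T_gt)
}

# shared slow fixtures, computed once per test run
acc_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = acc_cache)) assign(name, expr, envir = acc_cache)
  get(name, envir = acc_cache)
}
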