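#' Build the minimum spanning tree over a coarse skeleton
#'
#' Computes the MST of the complete Euclidean graph on the contracted
#' skeleton points (Prim's algorithm with on-the-fly distances, so the
#' complete graph is never materialized).  Exactly coincident duplicate
#' points are merged first.  Vertices of degree 1 are endpoints, vertices of
#' degree 3 or more are junctions; degree-2 chain vertices are never nodes.
#'
#' @param skeleton a `coarse_skeleton`, [point_cloud], or N x 3 matrix.
#' @return An object of class `skeleton_graph`: list with `vertices`
#'   (M x 3 matrix), `edges` (two-column index matrix), `lengths` (mm),
#'   `degree`, `endpoints`, `junctions`.
#' @export
build_mst <- function(skeleton) {
  P <- if (inherits(skeleton, "coarse_skeleton")) skeleton$points
       else as_points_matrix(skeleton)
  dup <- duplicated(P)
  if (any(dup)) {
    message("merging ", sum(dup), " coincident skeleton points before MST")
    P <- P[!dup, , drop = FALSE]
  }
  if (nrow(P) == 1L) {
    return(new_skeleton_graph(P, matrix(integer(0), 0, 2), numeric(0)))
  }
  mst <- cpp_prim_mst(P)
  new_skeleton_graph(P, cbind(mst$from, mst$to), mst$length)
}

new_skeleton_graph <- function(vertices, edges, lengths) {
  n <- nrow(vertices)
  deg <- tabulate(as.vector(edges), nbins = n)
  structure(list(vertices = vertices,
                 edges = matrix(as.integer(edges), ncol = 2),
                 lengths = as.numeric(lengths),
                 degree = deg,
                 endpoints = which(deg == 1L),
                 junctions = which(deg >= 3L)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d vertices, %d edges, %d endpoints, %d junctions\n",
              nrow(x$vertices), nrow(x$edges), length(x$endpoints),
              length(x$junctions)))
  invisible(x)
}

graph_as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$vertices), directed = FALSE)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, t(g$edges))
    igraph::E(ig)$weight <- g$lengths
  }
  ig
}

check_tree <- function(g) {
  n <- nrow(g$vertices)
  if (nrow(g$edges) != n - 1L)
    stop("skeleton graph is not a tree (|edges| != |vertices| - 1)")
  invisible(TRUE)
}

#' Mean MST edge length
#' @param g a `skeleton_graph`.
#' @return Mean edge length in mm (0 for a single vertex).
#' @export
mean_edge_length <- function(g) {
  if (length(g$lengths) == 0) return(0)
  mean(g$lengths)
}

#' Collapse clusters of nearby junctions
#'
#' Junction vertices (degree >= 3) whose pairwise geodesic (along-tree)
#' distance is below `merge_radius` are collapsed, together with the chain
#' vertices on the tree paths between them, into a single vertex placed at
#' the centroid of the cluster's junction vertices.  Incident edges are
#' reconnected and the result is again a tree.
#'
#' @param g a `skeleton_graph` (must be a tree).
#' @param merge_radius geodesic merge radius in mm; the scale-adaptive
#'   default is twice the mean MST edge length.
#' @return A simplified `skeleton_graph`.
#' @export
simplify_junctions <- function(g, merge_radius = 2 * mean_edge_length(g)) {
  check_tree(g)
  n <- nrow(g$vertices)
  jn <- g$junctions
  if (length(jn) < 2 || merge_radius <= 0) return(g)
  ig <- graph_as_igraph(g)
  gd <- igraph::distances(ig, v = jn, to = jn)
  close <- gd < merge_radius
  diag(close) <- FALSE
  if (!any(close)) return(g)
  # connected components of the "close junctions" relation
  cg <- igraph::graph_from_adjacency_matrix(close, mode = "undirected")
  comp <- igraph::components(cg)$membership
  group <- seq_len(n)             # vertex -> group representative
  centroid <- g$vertices
  for (ci in seq_len(max(comp))) {
    members <- jn[comp == ci]
    if (length(members) < 2) next
    # Steiner subtree: union of tree paths between cluster junctions
    sub <- unique(unlist(lapply(members[-1], function(v) {
      igraph::shortest_paths(ig, from = members[1], to = v,
                             weights = igraph::E(ig)$weight)$vpath[[1]]
    })))
    rep_v <- min(members)
    group[sub] <- rep_v
    centroid[rep_v, ] <- colMeans(g$vertices[members, , drop = FALSE])
  }
  keep <- sort(unique(group))
  if (length(keep) < 2)
    stop("junction merging collapsed the whole graph; lower merge_radius (",
         signif(merge_radius, 4), " mm)")
  remap <- match(group, keep)
  verts <- centroid[keep, , drop = FALSE]
  e <- cbind(remap[g$edges[, 1]], remap[g$edges[, 2]])
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  len <- sqrt(rowSums((verts[e[, 1], , drop = FALSE] -
                       verts[e[, 2], , drop = FALSE])^2))
  out <- new_skeleton_graph(verts, e, len)
  check_tree(out)
  out
}

#' Prune short terminal twigs
#'
#' Removes leaf chains (an endpoint plus its degree-2 tail) whose polyline
#' length up to the first junction is below `min_length`.  Tiny twigs are a
#' well-known artefact of MSTs over contracted point clouds: a point sitting
#' slightly off the skeletal curve attaches as a spurious one- or two-vertex
#' branch and would otherwise masquerade as a vessel branch.  A junction-free
#' path graph is never pruned.  Pruning repeats until no twig qualifies.
#'
#' @param g a `skeleton_graph` (tree).
#' @param min_length minimum branch length to survive, in mm.
#' @return A pruned `skeleton_graph`.
#' @export
prune_twigs <- function(g, min_length = 5) {
  check_tree(g)
  repeat {
    if (length(g$junctions) == 0 || min_length <= 0) return(g)
    adj <- adjacency_list(g)
    drop <- integer(0)
    for (ep in g$endpoints) {
      chain <- walk_chain(g, adj, ep)
      # chain runs from the endpoint to the first node; prune only if the far
      # end is a junction and the chain is short
      if (g$degree[chain[length(chain)]] >= 3 &&
          polyline_length(g$vertices[chain, , drop = FALSE]) < min_length) {
        drop <- c(drop, chain[-length(chain)])
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0) return(g)
    g <- drop_vertices(g, drop)
  }
}

adjacency_list <- function(g) {
  n <- nrow(g$vertices)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# from an endpoint, follow degree-2 vertices until the first node
# (junction or another endpoint); returns the vertex path including both ends
walk_chain <- function(g, adj, ep) {
  path <- ep
  prev <- 0L
  cur <- ep
  repeat {
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) break
    nxt <- nxt[1]
    path <- c(path, nxt)
    if (g$degree[nxt] != 2L) break
    prev <- cur
    cur <- nxt
  }
  path
}

polyline_length <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

drop_vertices <- function(g, drop) {
  keep <- setdiff(seq_len(nrow(g$vertices)), drop)
  remap <- match(seq_len(nrow(g$vertices)), keep)
  sel <- !(g$edges[, 1] %in% drop) & !(g$edges[, 2] %in% drop)
  e <- cbind(remap[g$edges[sel, 1]], remap[g$edges[sel, 2]])
  new_skeleton_graph(g$vertices[keep, , drop = FALSE], e, g$lengths[sel])
}

#' Split a skeleton tree into segments
#'
#' Decomposes the tree into maximal chains between nodes (endpoints of
#' degree 1 and junctions of degree >= 3).  Each branch is the unique tree
#' path -- equivalently the Dijkstra shortest path -- from an endpoint to its
#' geodesically nearest junction; junction-to-junction trunks are extracted
#' afterwards.  In a junction-free path graph the two endpoints pair with
#' each other.  Every non-node vertex belongs to exactly one segment; node
#' vertices are shared.
#'
#' @param g a `skeleton_graph` (tree) with at least 2 vertices.
#' @return List of `skeleton_segment` objects, branches first (ordered by
#'   their endpoint index), each a list with `vertices` (ordered index
#'   vector), `points` (ordered coordinates), `start_kind`/`end_kind`
#'   (`"endpoint"` or `"junction"`), `kind` (`"branch"` or `"trunk"`), and
#'   `length` (polyline mm).
#' @export
split_segments <- function(g) {
  check_tree(g)
  n <- nrow(g$vertices)
  if (n < 2) stop("need at least one vertex pair to split")
  adj <- adjacency_list(g)
  nodes <- sort(c(g$endpoints, g$junctions))
  segs <- list()
  seen <- character(0)
  for (v in nodes) {
    for (nb in sort(adj[[v]])) {
      # walk the chain leaving v through nb until the next node
      path <- c(v, nb)
      prev <- v; cur <- nb
      while (g$degree[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)[1]
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      key <- paste(min(path[1], path[length(path)]),
                   max(path[1], path[length(path)]),
                   min(path[2], path[length(path) - 1]),
                   max(path[2], path[length(path) - 1]))
      if (key %in% seen) next
      seen <- c(seen, key)
      kinds <- ifelse(g$degree[c(path[1], path[length(path)])] >= 3L,
                      "junction", "endpoint")
      # orient branches endpoint-first, trunks lower-index-first
      if ((kinds[1] == "junction" && kinds[2] == "endpoint") ||
          (kinds[1] == kinds[2] && path[1] > path[length(path)])) {
        path <- rev(path)
        kinds <- rev(kinds)
      }
      segs[[length(segs) + 1L]] <- structure(
        list(vertices = path,
             points = g$vertices[path, , drop = FALSE],
             start_kind = kinds[1], end_kind = kinds[2],
             kind = if (any(kinds == "endpoint")) "branch" else "trunk",
             length = polyline_length(g$vertices[path, , drop = FALSE])),
        class = "skeleton_segment")
    }
  }
  # branches first, stable by start vertex index
  ord <- order(vapply(segs, function(s) s$kind != "branch", logical(1)),
               vapply(segs, function(s) s$vertices[1], numeric(1)))
  segs[ord]
}
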