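#' Contraction parameters
#'
#' Parameters of the Laplacian point-cloud contraction stage.  The defaults
#' are the skeleton-contraction settings used for vascular point clouds:
#' down-sampling size 0.8 mm, 100 nearest neighbours, initial contraction
#' weight 0.5, initial attraction weight 4 (phantom profile; the human
#' profile uses 10), at most 10 iterations, termination ratio 0.003.
#'
#' @param voxel_edge down-sampling voxel edge in mm applied before
#'   contraction; `NA` disables down-sampling.
#' @param k_neighbors number of nearest neighbours used to build the
#'   Laplacian neighbourhood.
#' @param w_contract0 initial (scalar) contraction weight.
#' @param w_attract0 initial per-point attraction weight.
#' @param max_iter maximum number of contraction iterations.
#' @param termination_ratio stop when the relative change of the summed local
#'   neighbourhood extent between successive iterations falls below this.
#' @param contract_growth factor applied to the contraction weight each
#'   iteration.
#' @param w_contract_max cap on the contraction weight.  The default (8)
#'   keeps the smoothing term from overwhelming the attraction term on
#'   millimetre-scale vascular clouds: an uncapped geometric schedule
#'   collapses branches into the trunk, while a gentle cap leaves the coarse
#'   skeleton close to the true centreline (residual graph artefacts are
#'   handled downstream by twig pruning and the station validity gates).
#' @return A list of class `contraction_params`.
#' @export
contraction_params <- function(voxel_edge = 0.8, k_neighbors = 100,
                               w_contract0 = 0.5, w_attract0 = 4,
                               max_iter = 10, termination_ratio = 0.003,
                               contract_growth = 2.0, w_contract_max = 8) {
  if (k_neighbors < 4) stop("k_neighbors must be at least 4")
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (termination_ratio <= 0 || termination_ratio >= 1)
    stop("termination_ratio must lie in (0, 1)")
  if (w_contract0 < 0 || w_attract0 < 0)
    stop("weights must be non-negative")
  if (contract_growth <= 1) stop("contract_growth must exceed 1")
  structure(list(voxel_edge = voxel_edge, k_neighbors = as.integer(k_neighbors),
                 w_contract0 = w_contract0, w_attract0 = w_attract0,
                 max_iter = as.integer(max_iter),
                 termination_ratio = termination_ratio,
                 contract_growth = contract_growth,
                 w_contract_max = w_contract_max),
            class = "contraction_params")
}

#' k-nearest-neighbour table
#'
#' For each point, the indices of its `k` nearest Euclidean neighbours
#' (self excluded), distance ties broken by the lower index.
#'
#' @param points N x 3 matrix or [point_cloud].
#' @param k neighbourhood size; must be smaller than the number of points.
#' @return N x k integer matrix of neighbour indices.
#' @export
build_neighborhoods <- function(points, k) {
  P <- as_points_matrix(points)
  if (nrow(P) <= k)
    stop("need more points than k = ", k,
         " (have ", nrow(P), "); lower k_neighbors")
  cpp_knn(P, as.integer(k))
}

#' Umbrella Laplacian with inverse-distance weights
#'
#' Builds the sparse graph Laplacian over the symmetrized k-nearest-neighbour
#' graph.  Off-diagonal entries are `w_ij = 1 / max(||p_i - p_j||, eps)` for
#' each symmetrized neighbour pair, the diagonal is minus the row sum, so all
#' rows sum to zero.  Coincident points get epsilon-floored weights rather
#' than an abort.
#'
#' @param points N x 3 matrix or [point_cloud].
#' @param neighborhoods N x k index table from [build_neighborhoods].
#' @param eps distance floor in mm for coincident points.
#' @return Sparse N x N `Matrix::dgCMatrix`.
#' @export
build_laplacian <- function(points, neighborhoods, eps = 1e-6) {
  P <- as_points_matrix(points)
  n <- nrow(P)
  k <- ncol(neighborhoods)
  ii <- rep(seq_len(n), times = k)
  jj <- as.vector(neighborhoods)
  # symmetrize: unique unordered pairs
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  dup <- duplicated(a + (b - 1) * n)
  a <- a[!dup]; b <- b[!dup]
  d <- sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
  if (any(d < eps))
    warning("coincident points in Laplacian neighbourhood; weights floored")
  w <- 1 / pmax(d, eps)
  agg <- rowsum(c(w, w), c(a, b))
  degfull <- numeric(n)
  degfull[as.integer(rownames(agg))] <- agg[, 1]
  Matrix::sparseMatrix(i = c(a, b, seq_len(n)),
                       j = c(b, a, seq_len(n)),
                       x = c(w, w, -degfull),
                       dims = c(n, n))
}

#' Contract a point cloud to a coarse curve skeleton
#'
#' Iteratively solves the stacked least-squares system
#' `[W_L * L; W_H] X' = [0; W_H X]` for new positions, where `L` is the
#' inverse-distance umbrella Laplacian of the (fixed) k-nearest-neighbour
#' graph, `W_L` is a scalar contraction weight multiplied by
#' `contract_growth` each iteration (capped), and `W_H` is a per-point
#' attraction weight scaled by the ratio of initial to current local
#' neighbourhood extent.  Iteration stops at `max_iter` or when the relative
#' change of the summed local extent between iterations drops below the
#' termination ratio.
#'
#' @param pc a [point_cloud].
#' @param params a [contraction_params] object.
#' @return An object of class `coarse_skeleton`: list with `points`
#'   (contracted M x 3 positions), `source_index` (index of the originating
#'   down-sampled input point), `input_points` (the down-sampled cloud the
#'   contraction ran on), `iterations_run` and `shrink_trace` (per-iteration
#'   total-extent ratios relative to the initial extent).
#' @export
contract_point_cloud <- function(pc, params = contraction_params()) {
  work <- if (is.finite(params$voxel_edge %||% NA_real_)) {
    voxel_downsample(pc, params$voxel_edge)
  } else if (inherits(pc, "point_cloud")) pc else point_cloud(pc)
  X0 <- work$points
  n <- nrow(X0)
  k <- params$k_neighbors
  nb <- build_neighborhoods(X0, k)
  L <- build_laplacian(X0, nb)
  M <- Matrix::crossprod(L)   # fixed across iterations
  extent0 <- cpp_neighbor_extent(X0, nb)
  extent0 <- pmax(extent0, 1e-12)

  wl <- params$w_contract0
  wh <- rep(params$w_attract0, n)
  X <- X0
  S_prev <- sum(extent0)
  S_init <- S_prev
  trace <- numeric(0)
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    A <- wl^2 * M + Matrix::Diagonal(n, wh^2)
    rhs <- X * wh^2
    Xn <- as.matrix(Matrix::solve(A, rhs))
    if (!all(is.finite(Xn)))
      stop("contraction diverged (non-finite positions); parameters: ",
           sprintf("w_contract0=%g, w_attract0=%g, k=%d",
                   params$w_contract0, params$w_attract0, k))
    X <- Xn
    iters <- it
    extent <- cpp_neighbor_extent(X, nb)
    S <- sum(extent)
    trace <- c(trace, S / S_init)
    if (abs(S_prev - S) / S_prev < params$termination_ratio) break
    S_prev <- S
    wl <- min(wl * params$contract_growth, params$w_contract_max)
    wh <- params$w_attract0 * extent0 / pmax(extent, 1e-12)
  }
  structure(list(points = X, source_index = seq_len(n), input_points = work,
                 iterations_run = iters, shrink_trace = trace),
            class = "coarse_skeleton")
}

#' @export
print.coarse_skeleton <- function(x, ...) {
  cat(sprintf("coarse_skeleton: %d points, %d iterations, final extent ratio %.4f\n",
              nrow(x$points), x$iterations_run,
              if (length(x$shrink_trace)) utils::tail(x$shrink_trace, 1) else NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
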