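#' GO-ICP parameters
#'
#' Defaults follow the coarse-registration settings: the rotation cube covers
#' the full axis-angle space (corner at (-3.1416, -3.1416, -3.1416), width
#' 6.2832), the translation cube spans half a normalized unit about the
#' origin (corner at -0.5, width 1.0), the MSE stopping threshold is 0.001 in
#' normalized units squared, and the trimming fraction is 0.1.
#'
#' @param rot_corner corner of the rotation cube, axis-angle radians.
#' @param rot_width width of the rotation cube.
#' @param trans_corner corner of the translation cube, normalized units.
#' @param trans_width width of the translation cube.
#' @param mse_thresh stop once the incumbent trimmed MSE falls below this
#'   (normalized units squared).
#' @param trim_fraction fraction of worst correspondences discarded.
#' @param max_bnb_expansions budget on branch-and-bound node expansions.
#' @return A list of class `goicp_params`.
#' @export
goicp_params <- function(rot_corner = c(-3.1416, -3.1416, -3.1416),
                         rot_width = 6.2832,
                         trans_corner = c(-0.5, -0.5, -0.5),
                         trans_width = 1.0,
                         mse_thresh = 0.001, trim_fraction = 0.1,
                         max_bnb_expansions = 200000) {
  if (rot_width <= 0 || trans_width <= 0) stop("cube widths must be positive")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must lie in [0, 0.5)")
  structure(list(rot_corner = rot_corner, rot_width = rot_width,
                 trans_corner = trans_corner, trans_width = trans_width,
                 mse_thresh = mse_thresh, trim_fraction = trim_fraction,
                 max_bnb_expansions = as.integer(max_bnb_expansions)),
            class = "goicp_params")
}

#' Fine ICP parameters
#'
#' Defaults follow the fine-registration settings: at most 20 iterations, no
#' scale adjustment, no farthest-point filtering, a random sampling limit of
#' 50,000 source points, a final overlap ratio of 1 (all correspondences
#' kept), a degree-of-parallelism bound of 7 (results never depend on it),
#' and a minimum RMS decrease of 1e-6.
#'
#' @param max_iter iteration cap.
#' @param adjust_scale must remain `FALSE`; scale estimation is out of scope.
#' @param filter_farthest must remain `FALSE`.
#' @param random_sampling_limit uniform-subsample cap on source points.
#' @param final_overlap_ratio fraction of correspondences kept each step.
#' @param max_workers parallelism bound (a resource contract only).
#' @param min_rms_decrease convergence threshold on the RMS decrease.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iter = 20, adjust_scale = FALSE,
                       filter_farthest = FALSE,
                       random_sampling_limit = 50000,
                       final_overlap_ratio = 1.0, max_workers = 7,
                       min_rms_decrease = 1e-6) {
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (isTRUE(adjust_scale)) stop("scale adjustment is not supported")
  if (final_overlap_ratio <= 0 || final_overlap_ratio > 1)
    stop("final_overlap_ratio must lie in (0, 1]")
  structure(list(max_iter = as.integer(max_iter), adjust_scale = FALSE,
                 filter_farthest = isTRUE(filter_farthest),
                 random_sampling_limit = as.integer(random_sampling_limit),
                 final_overlap_ratio = final_overlap_ratio,
                 max_workers = as.integer(max_workers),
                 min_rms_decrease = min_rms_decrease),
            class = "icp_params")
}

new_registration_result <- function(transform, rmse, iterations, converged,
                                    stage_trace = list()) {
  structure(list(transform = transform, rmse = rmse,
                 iterations = iterations, converged = converged,
                 stage_trace = stage_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: rmse %.4f mm, %d iterations, converged: %s\n",
              x$rmse, x$iterations, x$converged))
  invisible(x)
}

#' Jointly normalize a source/target pair
#'
#' Both clouds are translated by the joint centroid and scaled by one common
#' factor (the reciprocal of the largest axis-aligned joint extent) so the
#' pair fits the normalized translation-cube domain.  The returned
#' `denormalize` closure maps a normalized-space rigid transform back to mm
#' space exactly.
#'
#' @param source,target point matrices (mm).
#' @return List with `source`, `target` (normalized matrices), `center`,
#'   `scale` (mm per normalized unit is `1/scale`), and
#'   `denormalize(T_normalized) -> T_mm`.
#' @export
normalize_pair <- function(source, target) {
  S <- as_points_matrix(source); Tg <- as_points_matrix(target)
  if (nrow(S) == 0 || nrow(Tg) == 0) stop("both clouds must be nonempty")
  all_pts <- rbind(S, Tg)
  ctr <- colMeans(all_pts)
  span <- max(apply(all_pts, 2, function(v) diff(range(v))))
  if (span <= 0) stop("zero-extent input; cannot normalize")
  s <- 1 / span
  norm_fun <- function(X) sweep(X, 2, ctr) * s
  denorm <- function(Tn) {
    rigid_transform(Tn$R, Tn$t / s + ctr - as.vector(Tn$R %*% ctr))
  }
  list(source = norm_fun(S), target = norm_fun(Tg), center = ctr, scale = s,
       denormalize = denorm)
}

#' Trimmed mean-squared nearest-neighbour error
#'
#' Squared nearest-neighbour distances from the transformed source to the
#' target, sorted; the mean of the smallest `(1 - trim_fraction)` fraction.
#'
#' @param source,target point matrices.
#' @param T a [rigid_transform] applied to the source.
#' @param trim_fraction fraction of the largest squared distances discarded.
#' @return Mean-squared error (units of the inputs squared).
#' @export
trimmed_residual <- function(source, target, T = rigid_transform(),
                             trim_fraction = 0.1) {
  S <- as_points_matrix(source)
  d2 <- cpp_nn(transform_points(S, T), as_points_matrix(target))$dist2
  m <- ceiling((1 - trim_fraction) * length(d2))
  if (m < 1) stop("trim_fraction leaves no correspondences")
  mean(sort(d2)[seq_len(m)])
}

# closed-form least-squares rigid fit mapping X onto Y (Kabsch/Umeyama,
# no scale)
fit_rigid <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cy - as.vector(R %*% cx))
}

# point-to-point ICP core; trim = 0 keeps all correspondences.  The residual
# trace is non-increasing: an update that would raise the RMS is rejected and
# the iteration stops there.
icp_core <- function(S, Tg, init, max_iter, min_rms_decrease, trim = 0,
                     on_degenerate = c("error", "stop")) {
  on_degenerate <- match.arg(on_degenerate)
  trimmed_rms <- function(d2) {
    if (trim > 0) {
      m <- ceiling((1 - trim) * length(d2))
      sqrt(mean(sort(d2)[seq_len(m)]))
    } else sqrt(mean(d2))
  }
  T_cur <- init
  prev_rms <- trimmed_rms(cpp_nn(transform_points(S, T_cur), Tg)$dist2)
  iters <- 0L
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Xs <- transform_points(S, T_cur)
    nn <- cpp_nn(Xs, Tg)
    keep <- seq_len(nrow(S))
    if (trim > 0) {
      m <- ceiling((1 - trim) * nrow(S))
      keep <- order(nn$dist2)[seq_len(m)]
    }
    if (length(unique(nn$index[keep])) < 3) {
      if (on_degenerate == "error")
        stop("degenerate correspondence set (< 3 distinct target points)")
      break      # keep the current transform; nothing sensible to fit
    }
    T_new <- fit_rigid(S[keep, , drop = FALSE],
                       Tg[nn$index[keep], , drop = FALSE])
    rms <- trimmed_rms(cpp_nn(transform_points(S, T_new), Tg)$dist2)
    if (rms > prev_rms) { converged <- TRUE; break }   # passed the local min
    T_cur <- T_new
    iters <- it
    trace <- c(trace, rms)
    dec <- prev_rms - rms
    prev_rms <- rms
    if (dec < min_rms_decrease) { converged <- TRUE; break }
  }
  list(transform = T_cur, rms = prev_rms, iterations = iters,
       converged = converged, trace = trace)
}

# small binary min-heap keyed on numeric priority, payload = list;
# storage is preallocated and doubled on demand (amortized O(log n) push)
heap_new <- function() new.env(parent = emptyenv())
heap_init <- function(h) {
  h$key <- numeric(1024); h$val <- vector("list", 1024); h$n <- 0L
  invisible(h)
}
heap_push <- function(h, key, val) {
  n <- h$n + 1L
  if (n > length(h$key)) {
    h$key <- c(h$key, numeric(length(h$key)))
    h$val <- c(h$val, vector("list", length(h$val)))
  }
  h$key[n] <- key; h$val[[n]] <- val; h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[p] <= h$key[i]) break
    tmpk <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tmpk
    tmpv <- h$val[[p]]; h$val[[p]] <- h$val[[i]]; h$val[[i]] <- tmpv
    i <- p
  }
}
heap_pop <- function(h) {
  n <- h$n
  if (n == 0L) return(NULL)
  top <- list(key = h$key[1], val = h$val[[1]])
  h$key[1] <- h$key[n]; h$val[[1]] <- h$val[[n]]
  h$val[n] <- list(NULL)
  h$n <- n <- n - 1L
  i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= n && h$key[l] < h$key[m]) m <- l
    if (r <= n && h$key[r] < h$key[m]) m <- r
    if (m == i) break
    tmpk <- h$key[m]; h$key[m] <- h$key[i]; h$key[i] <- tmpk
    tmpv <- h$val[[m]]; h$val[[m]] <- h$val[[i]]; h$val[[i]] <- tmpv
    i <- m
  }
  top
}

#' Globally optimal coarse registration (branch-and-bound ICP)
#'
#' Branch-and-bound over the joint rotation (axis-angle cube) and translation
#' cube.  Every node carries the trimmed MSE at its centre transform as an
#' upper bound and a per-point uncertainty-radius lower bound
#' (`max(d_i - gamma_rot_i - gamma_trans, 0)^2`, trimmed); incumbents are
#' refined with an inner trimmed ICP.  Nodes are expanded in best-first order
#' (priority queue on the lower bound) and split into octants of whichever
#' cube family currently contributes the larger uncertainty.  The search
#' terminates when the incumbent trimmed MSE reaches `mse_thresh`, when the
#' bounds close, or at the expansion budget (then `converged = FALSE`).
#'
#' @param source,target point matrices in mm (normalized internally).
#' @param params a [goicp_params] object.
#' @return A `registration_result`; `transform` maps source onto target in
#'   mm space, `rmse` is the untrimmed nearest-neighbour RMSE in mm, and
#'   `stage_trace` records the normalized-space trimmed MSE.
#' @export
goicp_coarse <- function(source, target, params = goicp_params()) {
  S0 <- as_points_matrix(source); T0 <- as_points_matrix(target)
  np <- normalize_pair(S0, T0)
  # the branch-and-bound works in the units of the original GO-ICP tool,
  # where the data spans [-1, 1]^3 (twice the normalize_pair frame): the
  # MSEThresh and translation-cube values are calibrated to that convention
  S <- 2 * np$source; Tg <- 2 * np$target
  trim <- params$trim_fraction
  gr_of <- function(sr) 2 * sin(min(sqrt(3) * sr / 2, pi / 2))
  refine <- function(T) {
    res <- icp_core(S, Tg, T, max_iter = 30, min_rms_decrease = 1e-9,
                    trim = trim, on_degenerate = "stop")
    list(T = res$transform, mse = res$rms^2)
  }
  # bounds for a batch of candidate nodes: stacked rotations + translations
  new_rigid <- function(R, t) {
    structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
  }
  bounds_for <- function(r0s, t0s, srs, sts) {
    K <- nrow(t0s)
    Rs <- do.call(rbind, lapply(seq_len(K),
                                function(k) rotation_exp(r0s[k, ])))
    b <- cpp_goicp_bounds(S, Tg, Rs, t0s,
                          vapply(srs, gr_of, numeric(1)),
                          sqrt(3) * sts, trim)
    list(lb = b[, 1], ub = b[, 2], Rs = Rs)
  }

  r_c <- params$rot_corner + params$rot_width / 2
  t_c <- params$trans_corner + params$trans_width / 2
  root <- list(r0 = r_c, sr = params$rot_width / 2,
               t0 = t_c, st = params$trans_width / 2)

  b0 <- bounds_for(matrix(root$r0, 1), matrix(root$t0, 1), root$sr, root$st)
  best <- list(T = new_rigid(b0$Rs, root$t0), mse = b0$ub[1])
  pool <- list()
  remember <- function(cand) {
    # keep a small pool of distinct refined incumbents for the caller to
    # re-rank with a symmetric criterion
    for (i in seq_along(pool)) {
      ang <- rotation_angle(t(pool[[i]]$T$R) %*% cand$T$R)
      dt <- sqrt(sum((pool[[i]]$T$t - cand$T$t)^2))
      if (ang < 5 * pi / 180 && dt < 0.05) {
        if (cand$mse < pool[[i]]$mse) pool[[i]] <<- cand
        return(invisible())
      }
    }
    pool[[length(pool) + 1L]] <<- cand
    invisible()
  }
  ref <- refine(best$T)
  remember(ref)
  if (ref$mse < best$mse) best <- ref
  expansions <- 0L
  converged <- best$mse <= params$mse_thresh
  h <- heap_init(heap_new())
  heap_push(h, b0$lb[1], root)
  rmax <- max(sqrt(rowSums(S^2)))

  while (!converged && expansions < params$max_bnb_expansions) {
    top <- heap_pop(h)
    if (is.null(top)) { converged <- TRUE; break }       # bounds closed
    if (top$key >= best$mse - 1e-12) { converged <- TRUE; break }
    node <- top$val
    expansions <- expansions + 1L
    # periodically polish the most promising region with the inner ICP:
    # the queue concentrates on low-lower-bound nodes, so their centres are
    # good starts and incumbents improve long before the bounds close
    if (expansions %% 10L == 1L) {
      cand <- refine(new_rigid(rotation_exp(node$r0), node$t0))
      remember(cand)
      if (cand$mse < best$mse) best <- cand
      if (best$mse <= params$mse_thresh) { converged <- TRUE; break }
    }
    # split the cube family with the larger current uncertainty
    split_rot <- gr_of(node$sr) * rmax >= sqrt(3) * node$st
    half <- if (split_rot) node$sr / 2 else node$st / 2
    offs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * half
    if (split_rot) {
      r0s <- sweep(offs, 2, node$r0, `+`)
      # drop rotation cubes entirely outside the pi-ball (redundant region)
      live <- sqrt(rowSums(r0s^2)) - sqrt(3) * half <= pi
      r0s <- r0s[live, , drop = FALSE]
      if (nrow(r0s) == 0) next
      t0s <- matrix(node$t0, nrow(r0s), 3, byrow = TRUE)
      srs <- rep(half, nrow(r0s)); sts <- rep(node$st, nrow(r0s))
    } else {
      t0s <- sweep(offs, 2, node$t0, `+`)
      r0s <- matrix(node$r0, 8, 3, byrow = TRUE)
      srs <- rep(node$sr, 8); sts <- rep(half, 8)
    }
    bb <- bounds_for(r0s, t0s, srs, sts)
    for (q in seq_len(nrow(t0s))) {
      if (bb$ub[q] < best$mse) {
        T_q <- new_rigid(bb$Rs[(3 * q - 2):(3 * q), ], t0s[q, ])
        best <- list(T = T_q, mse = bb$ub[q])
        cand <- refine(T_q)
        remember(cand)
        if (cand$mse < best$mse) best <- cand
        if (best$mse <= params$mse_thresh) { converged <- TRUE; break }
      }
      if (bb$lb[q] < best$mse - 1e-12) {
        heap_push(h, bb$lb[q],
                  list(r0 = r0s[q, ], sr = srs[q], t0 = t0s[q, ],
                       st = sts[q]))
      }
    }
  }
  to_mm <- function(Tn) {
    Tn$t <- Tn$t / 2                # back to the normalize_pair frame
    np$denormalize(Tn)
  }
  T_mm <- to_mm(best$T)
  d2_mm <- cpp_nn(transform_points(S0, T_mm), T0)$dist2
  pool <- pool[order(vapply(pool, `[[`, numeric(1), "mse"))]
  pool <- pool[seq_len(min(5L, length(pool)))]
  res <- new_registration_result(T_mm, sqrt(mean(d2_mm)), expansions,
                                 converged,
                                 stage_trace =
                                   list(goicp_trimmed_mse = best$mse))
  res$candidates <- lapply(pool, function(p) to_mm(p$T))
  res
}

#' Fine registration with point-to-point ICP
#'
#' Iterates nearest-neighbour correspondence and closed-form least-squares
#' rigid updates from the initial transform, keeping all correspondences
#' (no scale, no farthest-point filtering).  If the source exceeds
#' `random_sampling_limit` a seeded uniform subsample is used.  Stops at the
#' iteration cap or when the RMS decrease falls below `min_rms_decrease`.
#'
#' @param source,target point matrices in mm.
#' @param init initial [rigid_transform].
#' @param params an [icp_params] object.
#' @param seed seed for the subsampling stream (used only above the sampling
#'   limit).
#' @return A `registration_result` with the mm-space transform and untrimmed
#'   nearest-neighbour RMSE.
#' @export
icp_fine <- function(source, target, init = rigid_transform(),
                     params = icp_params(), seed = 0) {
  S <- as_points_matrix(source); Tg <- as_points_matrix(target)
  if (nrow(S) > params$random_sampling_limit) {
    with_preserved_rng(seed, {
      S <- S[sort(sample.int(nrow(S), params$random_sampling_limit)), ,
             drop = FALSE]
    })
  }
  res <- icp_core(S, Tg, init, params$max_iter, params$min_rms_decrease,
                  trim = 0)
  new_registration_result(res$transform, res$rms, res$iterations,
                          res$converged,
                          stage_trace = list(icp_rms = res$trace))
}

#' Two-stage registration of feature-curve sets
#'
#' Flattens both curve lists to weighted point sets, runs the branch-and-
#' bound coarse stage and then the fine ICP stage initialized at the coarse
#' result.  The reported result is never worse than the coarse stage alone.
#'
#' @param source_curves,target_curves lists of `feature_curve` objects.
#' @param goicp a [goicp_params] object.
#' @param icp an [icp_params] object.
#' @param seed seed for the weighted-resampling and subsampling streams.
#' @return A `registration_result`; `stage_trace` holds both stages.
#' @export
register_features <- function(source_curves, target_curves,
                              goicp = goicp_params(), icp = icp_params(),
                              seed = 0) {
  S <- flatten_curves(source_curves, seed = seed)
  Tg <- flatten_curves(target_curves, seed = seed + 1)
  coarse <- goicp_coarse(S, Tg, goicp)
  # polish every distinct coarse incumbent and re-rank by the symmetric
  # untrimmed residual: a wrong partial overlay can win the trimmed
  # directed objective, but leaves much of the other cloud unexplained
  inits <- coarse$candidates %||% list(coarse$transform)
  sym_rmse <- function(T) {
    (sqrt(mean(cpp_nn(transform_points(S, T), Tg)$dist2)) +
     sqrt(mean(cpp_nn(transform_points(Tg, invert_transform(T)), S)$dist2))) / 2
  }
  fine <- NULL; fine_score <- Inf
  for (init in inits) {
    cand <- icp_fine(S, Tg, init = init, params = icp, seed = seed + 2)
    sc <- sym_rmse(cand$transform)
    if (sc < fine_score) { fine <- cand; fine_score <- sc }
  }
  res <- if (fine$rmse <= coarse$rmse) fine else coarse
  new_registration_result(res$transform, res$rmse,
                          coarse$iterations + fine$iterations,
                          coarse$converged && fine$converged,
                          stage_trace = list(coarse_rmse = coarse$rmse,
                                             fine_rmse = fine$rmse,
                                             sym_rmse = fine_score,
                                             coarse = coarse$stage_trace,
                                             fine = fine$stage_trace))
}
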