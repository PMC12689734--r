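#' Segmentation and feature-curve parameters
#'
#' @param k_pca neighbourhood size for the PCA principal-direction estimate
#'   used to order a skeleton segment (default 20).
#' @param assign_radius search radius in mm around each skeleton point when
#'   collecting original vascular points (default 15).
#' @param end_downsample_k keep every k-th sample on terminal branch curves
#'   (default 5; applied in the human profile).
#' @param curve_samples number of uniform samples drawn from each fitted
#'   quadratic feature curve (default 25).
#' @param center_spacing arc-length spacing in mm between skeleton points
#'   used as segmentation centres (default 2.5).
#' @param min_branch_length terminal branches of the skeleton tree shorter
#'   than this (mm) are pruned as contraction artefacts (default 5).
#' @param cone_half_angle half-angle in degrees of the search cone about the
#'   vertical direction used to find the wall points A and B (default 15).
#' @param max_sample_dist curve samples farther than this (mm) from the
#'   segment's member vascular points are discarded as off-vessel artefacts
#'   (default 4, about the largest vessel radius plus the noise scale: a
#'   sample on a vessel axis lies within one radius of the lumen surface).
#' @param junction_margin centres closer than this (mm) to a junction vertex
#'   of the skeleton graph are discarded: their search balls mix points of
#'   two or more vessels, so their centroids sit between the lumens rather
#'   than on either axis (default 5).
#' @param max_angular_gap centres whose member points leave an angular gap
#'   larger than this (degrees) around the local axis are discarded as
#'   partial cross-sections: a half-seen lumen biases its centroid toward
#'   the visible wall, so such centres would systematically displace the
#'   curve (default 200; full rings with random dropout stay well below it).
#' @param min_station_points stations with fewer member points than this are
#'   discarded; a centroid of a handful of surface points is too noisy to
#'   anchor the curve (default 5).
#' @param refine_passes number of centre-recalculation passes: each pass
#'   re-assigns the original points to the current centres and recomputes the
#'   refined centres, pulling centres that started far off the lumen (for
#'   example near junction blends of the coarse skeleton) onto the vessel
#'   axis (default 2; with the validity gates a second pass pulls high-leverage
#'   end centres onto the axis; default 4).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(k_pca = 20, assign_radius = 15,
                                end_downsample_k = 5, curve_samples = 25,
                                center_spacing = 2.5, min_branch_length = 5,
                                cone_half_angle = 15, max_sample_dist = 4,
                                max_angular_gap = 200, junction_margin = 5,
                                min_station_points = 5, refine_passes = 4) {
  if (k_pca < 3) stop("k_pca must be at least 3")
  if (assign_radius <= 0) stop("assign_radius must be positive")
  if (end_downsample_k < 1) stop("end_downsample_k must be at least 1")
  if (curve_samples < 2) stop("curve_samples must be at least 2")
  structure(list(k_pca = as.integer(k_pca), assign_radius = assign_radius,
                 end_downsample_k = as.integer(end_downsample_k),
                 curve_samples = as.integer(curve_samples),
                 center_spacing = center_spacing,
                 min_branch_length = min_branch_length,
                 cone_half_angle = cone_half_angle,
                 max_sample_dist = max_sample_dist,
                 max_angular_gap = max_angular_gap,
                 junction_margin = junction_margin,
                 min_station_points = as.integer(min_station_points),
                 refine_passes = as.integer(refine_passes)),
            class = "segmentation_params")
}

#' Order a skeleton segment along its principal direction
#'
#' The principal direction is the leading eigenvector of the segment's
#' covariance; points are sorted by scalar projection onto it, with the sign
#' chosen so that the segment's first (start-node) point projects lowest.
#'
#' @param points segment point coordinates (n x 3), or a `skeleton_segment`.
#' @param k_pca neighbourhood-size parameter carried in the configuration;
#'   the covariance estimate uses all segment points (equivalent to
#'   min(k_pca, n) when segments are short).
#' @return List with `points` (sorted n x 3 matrix), `order` (permutation),
#'   and `axis` (unit principal direction).
#' @export
order_segment <- function(points, k_pca = 20) {
  P <- if (inherits(points, "skeleton_segment")) points$points
       else as_points_matrix(points)
  if (nrow(P) < 2) stop("segment needs at least 2 points")
  C <- colMeans(P)
  Pc <- sweep(P, 2, C)
  if (max(abs(Pc)) == 0) stop("zero-variance segment (all points coincident)")
  ev <- eigen(crossprod(Pc) / nrow(P), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  proj <- as.vector(Pc %*% axis)
  if (proj[1] > proj[length(proj)]) { axis <- -axis; proj <- -proj }
  ord <- order(proj)
  list(points = P[ord, , drop = FALSE], order = ord, axis = axis)
}

#' Assign original vascular points to skeleton points
#'
#' Each original point is assigned to its nearest skeleton point, and kept
#' only when that distance is within `assign_radius` (closed inclusion).
#' This resolves the overlap between consecutive search balls: no original
#' point appears in more than one set.
#'
#' @param original [point_cloud] or matrix of original vascular points.
#' @param skeleton_points ordered skeleton points (n x 3).
#' @param assign_radius search radius in mm.
#' @return A list of length `nrow(skeleton_points)`; element i holds the
#'   row indices of the original points claimed by skeleton point i (possibly
#'   empty).
#' @export
assign_vessel_points <- function(original, skeleton_points, assign_radius = 15) {
  O <- as_points_matrix(original)
  S <- as_points_matrix(skeleton_points)
  nn <- cpp_nn(O, S)
  ok <- nn$dist2 <= assign_radius^2
  idx <- nn$index
  out <- vector("list", nrow(S))
  hit <- which(ok)
  if (length(hit)) {
    sp <- split(hit, idx[hit])
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Recalculate a robust vessel centre point
#'
#' Given the original points `P` claimed by one skeleton point, the initial
#' centre `C` (centroid of `P`) and the local vessel axis, finds the two wall
#' points `A` and `B` of `P` closest to `C` within cones about the +/- second
#' principal (vertical) direction, takes half their separation `d/2` as a
#' radius, and recomputes the centre `C'` as the centroid of the members of
#' `P` within `d/2` of `C`.  Falls back to `C' = C` when the neighbour set is
#' empty or `P` is degenerate.
#'
#' @param P point set (m x 3 matrix), m >= 3 for a full refinement.
#' @param C initial centre; default the centroid of `P`.
#' @param axis local vessel axis direction (unit 3-vector); used only to keep
#'   the vertical estimate perpendicular to the vessel.
#' @param cone_half_angle half-angle of the A/B search cone, degrees.
#' @return List with `C_prime`, `A`, `B`, `d`, `n_inside` (size of the
#'   neighbour set) and `degenerate` flag.
#' @export
refine_center <- function(P, C = colMeans(P), axis = NULL,
                          cone_half_angle = 15) {
  P <- as_points_matrix(P)
  if (nrow(P) < 3)
    return(list(C_prime = C, A = NULL, B = NULL, d = NA_real_,
                n_inside = 0L, degenerate = TRUE))
  Pc <- sweep(P, 2, colMeans(P))
  S <- crossprod(Pc) / nrow(P)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] < 1e-18)
    return(list(C_prime = C, A = NULL, B = NULL, d = NA_real_,
                n_inside = 0L, degenerate = TRUE))
  vertical <- ev$vectors[, 2]
  if (!is.null(axis)) {
    # project out the axis component so the search stays cross-sectional
    v <- vertical - sum(vertical * axis) * axis
    if (sqrt(sum(v^2)) > 1e-9) vertical <- v / sqrt(sum(v^2))
  }
  rel <- sweep(P, 2, C)
  dist <- sqrt(rowSums(rel^2))
  cosang <- as.vector(rel %*% vertical) / pmax(dist, 1e-12)
  cmin <- cos(cone_half_angle * pi / 180)
  pick_wall <- function(cos_side) {
    cand <- which(cos_side >= cmin & dist > 0)
    if (length(cand) == 0) cand <- which(dist > 0)  # fallback: nearest overall
    cand[which.min(dist[cand])]
  }
  ia <- pick_wall(cosang)
  ib <- pick_wall(-cosang)
  A <- P[ia, ]; B <- P[ib, ]
  d <- sqrt(sum((A - B)^2))
  inside <- which(dist <= d / 2 + 1e-9)   # closed inclusion, fp-safe
  if (length(inside) == 0) {
    return(list(C_prime = C, A = A, B = B, d = d, n_inside = 0L,
                degenerate = FALSE))
  }
  list(C_prime = colMeans(P[inside, , drop = FALSE]), A = A, B = B, d = d,
       n_inside = length(inside), degenerate = FALSE)
}

# largest angular gap (degrees) of points around `axis` as seen from C;
# 360 for degenerate sets
angular_gap <- function(P, C, axis) {
  rel <- sweep(as_points_matrix(P), 2, C)
  rel <- rel - outer(as.vector(rel %*% axis), axis)
  r <- sqrt(rowSums(rel^2))
  ok <- r > 1e-9
  if (sum(ok) < 3) return(360)
  u <- unit_perp(axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  th <- sort(atan2(rel[ok, ] %*% v, rel[ok, ] %*% u))
  gaps <- diff(c(th, th[1] + 2 * pi))
  max(gaps) * 180 / pi
}

#' Fit a quadratic feature curve through centre points
#'
#' Each coordinate is fit by least squares as a quadratic polynomial in the
#' scalar parameter `t`, the projection of each centre onto the segment axis
#' affinely mapped to `[0, 1]`; the curve is then sampled at `curve_samples`
#' uniform `t` values.  With fewer than 3 centres the polyline is passed
#' through unchanged with a warning.
#'
#' @param centers ordered refined centre points (n x 3).
#' @param curve_samples number of uniform samples.
#' @param axis segment axis used for the parameterization; default the
#'   leading principal direction of the centres.
#' @param weight non-negative segment weight carried on the curve.
#' @param segment_kind `"branch"` or `"trunk"`.
#' @param t_range parameter interval to sample, in the normalized
#'   coordinates where the centres span `[0, 1]`.  Values slightly outside
#'   `[0, 1]` extrapolate the fitted quadratic; the feature pipeline uses
#'   this to recover the axial extent of the underlying vessel segment that
#'   the skeleton contraction shortens.
#' @return An object of class `feature_curve`: list with `samples`
#'   (curve_samples x 3), `weight`, `segment_kind`, `coefficients`
#'   (3 x 3 matrix, one column per coordinate).
#' @export
fit_feature_curve <- function(centers, curve_samples = 25, axis = NULL,
                              weight = 1, segment_kind = "trunk",
                              t_range = c(0, 1)) {
  X <- as_points_matrix(centers)
  if (nrow(X) < 3) {
    warning("fewer than 3 centres; passing polyline through unfitted")
    return(structure(list(samples = X, weight = weight,
                          segment_kind = segment_kind, coefficients = NULL),
                     class = "feature_curve"))
  }
  if (is.null(axis)) {
    Pc <- sweep(X, 2, colMeans(X))
    axis <- eigen(crossprod(Pc), symmetric = TRUE)$vectors[, 1]
  }
  t_raw <- as.vector(X %*% axis)
  rng <- range(t_raw)
  if (diff(rng) <= 0) stop("degenerate parameterization: zero axial extent")
  t <- (t_raw - rng[1]) / diff(rng)
  D <- cbind(1, t, t^2)
  coef <- qr.solve(D, X)          # least squares, 3 coefficients per coord
  tt <- seq(t_range[1], t_range[2], length.out = curve_samples)
  # inside [0,1] evaluate the quadratic; outside continue linearly along the
  # boundary tangent (quadratic extrapolation amplifies fit noise)
  tc <- pmin(pmax(tt, 0), 1)
  samples <- cbind(1, tc, tc^2) %*% coef
  out_lo <- tt < 0; out_hi <- tt > 1
  if (any(out_lo)) {
    d0 <- coef[2, ]                      # derivative at t = 0
    samples[out_lo, ] <- samples[out_lo, , drop = FALSE] +
      outer(tt[out_lo], d0)
  }
  if (any(out_hi)) {
    d1 <- coef[2, ] + 2 * coef[3, ]      # derivative at t = 1
    samples[out_hi, ] <- samples[out_hi, , drop = FALSE] +
      outer(tt[out_hi] - 1, d1)
  }
  structure(list(samples = samples, weight = weight,
                 segment_kind = segment_kind, coefficients = coef),
            class = "feature_curve")
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("feature_curve (%s): %d samples, weight %.3f, length %.1f mm\n",
              x$segment_kind, nrow(x$samples), x$weight,
              polyline_length(x$samples)))
  invisible(x)
}

#' Down-sample the ends of the vessel feature set
#'
#' On terminal branch curves every k-th sample is retained (the first and
#' last samples always survive); trunk curves are untouched.  This reduces
#' the influence of end capillaries on the registration.
#'
#' @param curves list of `feature_curve` objects.
#' @param end_downsample_k keep-every-k parameter (default 5).
#' @return The down-sampled list of curves.
#' @export
downsample_ends <- function(curves, end_downsample_k = 5) {
  k <- as.integer(end_downsample_k)
  if (k < 1) stop("end_downsample_k must be at least 1")
  if (k == 1) return(curves)
  lapply(curves, function(cv) {
    if (!identical(cv$segment_kind, "branch")) return(cv)
    n <- nrow(cv$samples)
    keep <- sort(unique(c(seq(1L, n, by = k), n)))
    cv$samples <- cv$samples[keep, , drop = FALSE]
    cv
  })
}

# pick skeleton vertices along an ordered segment at ~spacing mm arc-length,
# always keeping the first and last vertex
subsample_by_arclength <- function(P, spacing) {
  n <- nrow(P)
  if (n <= 2 || spacing <= 0) return(seq_len(n))
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  keep <- 1L
  last <- 0
  for (i in 2:(n - 1)) {
    if (s[i] - last >= spacing) { keep <- c(keep, i); last <- s[i] }
  }
  unique(c(keep, n))
}

#' Extract skeleton feature curves from a vascular point cloud
#'
#' Full feature pipeline: voxel down-sampling and Laplacian contraction to a
#' coarse skeleton, Euclidean MST with twig pruning and junction
#' simplification, segment splitting, PCA ordering, assignment of original
#' points to skeleton centres, robust centre refinement, and per-segment
#' quadratic curve fitting.  The human profile additionally weights each
#' curve by its normalized polyline length and uniformly down-samples the
#' ends of terminal branches; the phantom profile uses unit weights.
#'
#' @param pc a [point_cloud].
#' @param contraction a [contraction_params] object.
#' @param seg a [segmentation_params] object.
#' @param profile `"phantom"` or `"human"`.
#' @return List of `feature_curve` objects with attributes `skeleton` (the
#'   `coarse_skeleton`) and `graph` (the simplified `skeleton_graph`).
#' @export
extract_features <- function(pc, contraction = contraction_params(),
                             seg = segmentation_params(),
                             profile = c("phantom", "human")) {
  profile <- match.arg(profile)
  sk <- with_stage("contraction", contract_point_cloud(pc, contraction))
  g <- with_stage("skeleton_graph", {
    g <- build_mst(sk)
    g <- prune_twigs(g, seg$min_branch_length)
    simplify_junctions(g)
  })
  segments <- with_stage("skeleton_graph", split_segments(g))
  with_stage("features", {
    original <- sk$input_points$points
    # per-segment ordered centre skeleton points; the contraction shortens
    # segments axially, so extra candidate centres are placed past each end
    # along the end tangent -- those that collect no vascular points (or only
    # partial cross-sections) are dropped by the validity gates below
    seg_centers <- lapply(segments, function(sg) {
      o <- order_segment(sg$points, seg$k_pca)
      idx <- subsample_by_arclength(o$points, seg$center_spacing)
      ctr <- o$points[idx, , drop = FALSE]
      n <- nrow(ctr)
      if (n >= 2) {
        q <- max(2L, ceiling(0.35 * n))
        lo_dir <- ctr[1, ] - ctr[2, ]
        hi_dir <- ctr[n, ] - ctr[n - 1, ]
        lo_dir <- lo_dir / max(sqrt(sum(lo_dir^2)), 1e-9)
        hi_dir <- hi_dir / max(sqrt(sum(hi_dir^2)), 1e-9)
        ext_lo <- sweep(outer(rev(seq_len(q)) * seg$center_spacing, lo_dir),
                        2, ctr[1, ], `+`)
        ext_hi <- sweep(outer(seq_len(q) * seg$center_spacing, hi_dir),
                        2, ctr[n, ], `+`)
        ctr <- rbind(ext_lo, ctr, ext_hi)
      }
      list(points = ctr, axis = o$axis, kind = sg$kind)
    })
    all_centers <- do.call(rbind, lapply(seg_centers, `[[`, "points"))
    seg_id <- rep(seq_along(seg_centers),
                  vapply(seg_centers, function(s) nrow(s$points), integer(1)))
    axes <- do.call(rbind, lapply(seg_centers, function(s) {
      matrix(s$axis, nrow(s$points), 3, byrow = TRUE)
    }))
    # centre recalculation: assign originals to the current centres, refine,
    # and repeat so centres that started off the lumen converge onto the axis
    valid <- rep(TRUE, nrow(all_centers))
    for (pass in seq_len(max(1L, seg$refine_passes))) {
      assigned <- assign_vessel_points(original, all_centers,
                                       seg$assign_radius)
      for (j in seq_len(nrow(all_centers))) {
        members <- assigned[[j]]
        if (length(members) < seg$min_station_points) {
          valid[j] <- FALSE
          next
        }
        Pj <- original[members, , drop = FALSE]
        all_centers[j, ] <- refine_center(Pj, C = colMeans(Pj),
                                          axis = axes[j, ],
                                          cone_half_angle =
                                            seg$cone_half_angle)$C_prime
        # partial cross-sections bias the centroid toward the seen wall
        valid[j] <- angular_gap(Pj, all_centers[j, ], axes[j, ]) <=
          seg$max_angular_gap
      }
    }
    # stations near a junction mix points of several vessels and sit between
    # the lumens; drop them
    if (length(g$junctions) > 0 && seg$junction_margin > 0) {
      jd <- sqrt(cpp_nn(all_centers,
                        g$vertices[g$junctions, , drop = FALSE])$dist2)
      valid <- valid & jd > seg$junction_margin
    }

    curves <- list()
    for (si in seq_along(seg_centers)) {
      rows <- which(seg_id == si & valid)
      sc <- seg_centers[[si]]
      refined <- all_centers[rows, , drop = FALSE]
      if (nrow(refined) < 2) next
      members_all <- unlist(assigned[rows])
      cv <- suppressWarnings(
        fit_feature_curve(refined, seg$curve_samples, axis = sc$axis,
                          weight = 1, segment_kind = sc$kind))
      # drop samples that stray off the vessel (bad extrapolation or a
      # mis-attributed segment)
      if (length(members_all) >= 3 && nrow(cv$samples) >= 2) {
        dd <- sqrt(cpp_nn(cv$samples,
                          original[members_all, , drop = FALSE])$dist2)
        cv$samples <- cv$samples[dd <= seg$max_sample_dist, , drop = FALSE]
      }
      if (nrow(cv$samples) >= 2) curves[[length(curves) + 1L]] <- cv
    }
    if (length(curves) == 0) stop("no feature curves could be extracted")
    if (profile == "human") {
      len <- vapply(curves, function(cv) polyline_length(cv$samples), numeric(1))
      wts <- len / sum(len)
      curves <- Map(function(cv, w) { cv$weight <- w; cv }, curves, wts)
      curves <- downsample_ends(curves, seg$end_downsample_k)
    }
    attr(curves, "skeleton") <- sk
    attr(curves, "graph") <- g
    curves
  })
}

# evaluate expr, prefixing errors with the pipeline stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Flatten feature curves to a weighted point matrix
#'
#' Curve weights are realized by proportional resampling: each curve
#' contributes a number of points proportional to its weight (seeded, so the
#' result is deterministic), drawn from its samples.
#'
#' @param curves list of `feature_curve` objects.
#' @param total_budget total number of points to emit; default keeps roughly
#'   all samples when weights are uniform.
#' @param seed integer seed for the subsampling stream.
#' @return N x 3 matrix of feature points.
#' @export
flatten_curves <- function(curves, total_budget = NULL, seed = 0) {
  ns <- vapply(curves, function(cv) nrow(cv$samples), integer(1))
  w <- vapply(curves, function(cv) cv$weight, numeric(1))
  if (all(w == w[1])) return(do.call(rbind, lapply(curves, `[[`, "samples")))
  if (is.null(total_budget)) total_budget <- sum(ns)
  w <- w / sum(w)
  counts <- pmax(2L, round(total_budget * w))
  out <- vector("list", length(curves))
  with_preserved_rng(seed, {
    for (i in seq_along(curves)) {
      S <- curves[[i]]$samples
      n <- nrow(S)
      take <- if (counts[i] >= n) seq_len(n)
              else sort(sample.int(n, counts[i]))
      out[[i]] <- S[take, , drop = FALSE]
    }
  })
  do.call(rbind, out)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
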