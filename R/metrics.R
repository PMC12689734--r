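#' Skeleton RMSE between feature-curve sets
#'
#' Root-mean-square of the distances from each transformed sample of `a` to
#' its nearest sample of `b` (the directed nearest-neighbour RMSE that the
#' fine ICP stage minimizes).
#'
#' @param a,b lists of `feature_curve` objects, or point matrices.
#' @param T a [rigid_transform] applied to `a` (default identity).
#' @return RMSE in mm.
#' @export
skeleton_rmse <- function(a, b, T = rigid_transform()) {
  A <- flatten_any(a); B <- flatten_any(b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both feature sets must be nonempty")
  sqrt(mean(cpp_nn(transform_points(A, T), B)$dist2))
}

flatten_any <- function(x) {
  if (is.list(x) && !inherits(x, "point_cloud") && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "feature_curve"))) {
    return(do.call(rbind, lapply(x, `[[`, "samples")))
  }
  as_points_matrix(x)
}

#' Target registration error at a tumour centre
#'
#' Euclidean distance between the transformed moving-frame centre and the
#' fixed-frame centre.
#'
#' @param center_moving,center_fixed 3-vectors in mm.
#' @param T a [rigid_transform] mapping the moving frame onto the fixed.
#' @return TRE in mm.
#' @export
target_registration_error <- function(center_moving, center_fixed,
                                      T = rigid_transform()) {
  p <- as.vector(T$R %*% as.numeric(center_moving)) + T$t
  sqrt(sum((p - as.numeric(center_fixed))^2))
}

#' Dice coefficient and volume similarity of two voxel masks
#'
#' `dice = 2|A&B| / (|A| + |B|)`; `VS = 1 - ||A| - |B|| / (|A| + |B|)`.
#' Masks must share one voxel grid.
#'
#' @param mask_a,mask_b logical (or 0/1) arrays of identical dimension.
#' @return List with `dice` and `volume_similarity`; both `NA` when the two
#'   masks are empty (undefined, reported as absent rather than zero).
#' @export
dice_and_vs <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share one voxel grid")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    return(list(dice = NA_real_, volume_similarity = NA_real_))
  list(dice = 2 * sum(a & b) / (na + nb),
       volume_similarity = 1 - abs(na - nb) / (na + nb))
}

#' Surface Dice at tolerance
#'
#' The symmetric surface overlap: the fraction of surface samples of each
#' set lying within `tau` of the other, combined as
#' `(|S_a within tau of S_b| + |S_b within tau of S_a|) / (|S_a| + |S_b|)`.
#' The 5 mm default matches the clinical ablation margin (SDV5).
#'
#' @param surface_a,surface_b surface sample matrices (n x 3, mm).
#' @param tau tolerance in mm.
#' @return Value in `[0, 1]`.
#' @export
surface_dice <- function(surface_a, surface_b, tau = 5) {
  if (tau <= 0) stop("tau must be positive")
  A <- as_points_matrix(surface_a); B <- as_points_matrix(surface_b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both surfaces must be nonempty")
  hits_ab <- sum(cpp_nn(A, B)$dist2 <= tau^2)
  hits_ba <- sum(cpp_nn(B, A)$dist2 <= tau^2)
  (hits_ab + hits_ba) / (nrow(A) + nrow(B))
}

#' Voxelize spheres on a regular grid
#'
#' @param centers matrix of sphere centres (n x 3, mm).
#' @param radii sphere radii in mm (recycled).
#' @param origin grid origin (coordinate of the centre of voxel [1,1,1]).
#' @param spacing voxel edge in mm (default 1).
#' @param dims grid dimensions (3 integers).
#' @return Logical array of dimension `dims`.
#' @export
voxelize_spheres <- function(centers, radii, origin, spacing = 1, dims) {
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  centers <- as_points_matrix(centers)
  radii <- rep_len(radii, nrow(centers))
  mask <- array(FALSE, dim = dims)
  ax <- lapply(1:3, function(d) origin[d] + spacing * (seq_len(dims[d]) - 1))
  for (i in seq_len(nrow(centers))) {
    dx2 <- (ax[[1]] - centers[i, 1])^2
    dy2 <- (ax[[2]] - centers[i, 2])^2
    dz2 <- (ax[[3]] - centers[i, 3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radii[i]^2
    mask <- mask | inside
  }
  mask
}

#' Sample points on sphere surfaces
#'
#' Deterministic Fibonacci-lattice sampling, used to compare tumour surfaces
#' with [surface_dice].
#'
#' @param centers matrix of sphere centres (n x 3, mm).
#' @param radii sphere radii in mm (recycled).
#' @param n_per_sphere samples per sphere.
#' @return Matrix of surface points.
#' @export
sphere_surface_points <- function(centers, radii, n_per_sphere = 200) {
  centers <- as_points_matrix(centers)
  radii <- rep_len(radii, nrow(centers))
  i <- seq_len(n_per_sphere) - 0.5
  phi <- acos(1 - 2 * i / n_per_sphere)
  theta <- pi * (1 + sqrt(5)) * i
  unit <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    sweep(unit * radii[j], 2, centers[j, ], `+`)
  }))
}

#' Evaluate a registration against a case's tumour markers
#'
#' Computes the feature-set skeleton RMSE, the per-tumour target
#' registration error, and -- when tumour radii are available -- Dice,
#' volume similarity and surface Dice at tolerance between the fixed tumour
#' masks and the transformed moving tumour masks, voxelized on a shared
#' 1 mm grid.
#'
#' @param case an `eval_case` (see [make_case]).
#' @param T the estimated [rigid_transform] (moving onto fixed).
#' @param features_moving,features_fixed optional feature-curve lists; when
#'   both are given the skeleton RMSE between them under `T` is reported.
#' @param tau surface-Dice tolerance in mm.
#' @param mask_spacing voxel edge for the mask metrics, mm.
#' @return List of class `evaluation_report` with `rmse`, `tre_per_tumor`,
#'   `dice`, `volume_similarity`, `surface_dice_tau`, `tau`.  Metrics whose
#'   inputs are absent are `NA`.
#' @export
evaluate_case <- function(case, T, features_moving = NULL,
                          features_fixed = NULL, tau = 5, mask_spacing = 1) {
  rmse <- if (!is.null(features_moving) && !is.null(features_fixed))
    skeleton_rmse(features_moving, features_fixed, T) else NA_real_
  tre <- NA_real_
  dice <- NA_real_; vs <- NA_real_; sd_tau <- NA_real_
  if (!is.null(case$tumor_centers_moving) &&
      !is.null(case$tumor_centers_fixed)) {
    cm <- as_points_matrix(case$tumor_centers_moving)
    cf <- as_points_matrix(case$tumor_centers_fixed)
    if (nrow(cm) != nrow(cf))
      stop("tumour-centre lists must have equal length")
    tre <- vapply(seq_len(nrow(cm)), function(i) {
      target_registration_error(cm[i, ], cf[i, ], T)
    }, numeric(1))
    if (!is.null(case$tumor_radii)) {
      moved <- transform_points(cm, T)
      r <- rep_len(case$tumor_radii, nrow(cm))
      lo <- pmin(apply(moved - r, 2, min), apply(cf - r, 2, min)) - 2
      hi <- pmax(apply(moved + r, 2, max), apply(cf + r, 2, max)) + 2
      dims <- pmax(2L, as.integer(ceiling((hi - lo) / mask_spacing)) + 1L)
      mk_f <- voxelize_spheres(cf, r, lo, mask_spacing, dims)
      mk_m <- voxelize_spheres(moved, r, lo, mask_spacing, dims)
      dv <- dice_and_vs(mk_f, mk_m)
      dice <- dv$dice; vs <- dv$volume_similarity
      sd_tau <- surface_dice(sphere_surface_points(cf, r),
                             sphere_surface_points(moved, r), tau)
    }
  }
  structure(list(rmse = rmse, tre_per_tumor = tre, dice = dice,
                 volume_similarity = vs, surface_dice_tau = sd_tau,
                 tau = tau),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: rmse %.3f mm, mean TRE %.3f mm, dice %.3f, VS %.3f, SD@%gmm %.3f\n",
              x$rmse, mean(x$tre_per_tumor), x$dice, x$volume_similarity,
              x$tau, x$surface_dice_tau))
  invisible(x)
}
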