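#' Specification of a synthetic branching vessel tree
#'
#' The defaults describe a liver-portal-vein-scale phantom: a ~150 mm gently
#' curved trunk with 3-8 side branches of 40-80 mm, trunk radius 3 mm and
#' branch radius 2 mm, so millimetre tolerances downstream are meaningful.
#'
#' @param n_branches number of side branches (>= 0).
#' @param trunk_length trunk arc length in mm.
#' @param branch_length_range min/max branch length in mm.
#' @param branch_angle_range min/max branch take-off angle in degrees.
#' @param radius_trunk,radius_branch tube radii in mm.
#' @param curvature magnitude of the quadratic bend of the trunk (mm of
#'   lateral offset at the far end).
#' @param seed integer seed; the whole tree is a deterministic function of it.
#' @return A list of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_branches = 5, trunk_length = 150,
                             branch_length_range = c(40, 80),
                             branch_angle_range = c(35, 70),
                             radius_trunk = 3, radius_branch = 2,
                             curvature = 15, seed = 0) {
  if (n_branches < 0) stop("n_branches must be non-negative")
  if (trunk_length <= 0 || radius_trunk <= 0 || radius_branch <= 0)
    stop("lengths and radii must be positive")
  structure(list(n_branches = as.integer(n_branches),
                 trunk_length = trunk_length,
                 branch_length_range = branch_length_range,
                 branch_angle_range = branch_angle_range,
                 radius_trunk = radius_trunk, radius_branch = radius_branch,
                 curvature = curvature, seed = as.integer(seed)),
            class = "vessel_tree_spec")
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

unit_perp <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * v) * v
  p / sqrt(sum(p^2))
}

# quadratic space curve from `start` along `dir` with lateral bend `bend_vec`
# at the far end; returns a polyline sampled at ~1 mm steps
quadratic_polyline <- function(start, dir, length, bend_vec, step = 1) {
  n <- max(2L, ceiling(length / step) + 1L)
  t <- seq(0, 1, length.out = n)
  P <- outer(t * length, dir) + outer(t^2, bend_vec)
  sweep(P, 2, start, `+`)
}

#' Generate a branching vessel-tree centreline
#'
#' The trunk is a quadratic space curve; branches sprout at seeded arc-length
#' positions with seeded take-off angles and azimuths (azimuths are re-drawn
#' a bounded number of times if two branches would leave the trunk within 30
#' degrees of each other at nearby stations).  Deterministic per seed.
#'
#' @param spec a [vessel_tree_spec].
#' @return An object of class `vessel_tree`: a list of components, each with
#'   `points` (polyline, mm), `radius`, and `kind` (`"trunk"`/`"branch"`).
#' @export
generate_vessel_tree <- function(spec) {
  with_preserved_rng(spec$seed, {
    bend_dir <- unit_perp(c(0, 0, 1))
    az0 <- stats::runif(1, 0, 2 * pi)
    bend_dir <- rotation_axis_angle(c(0, 0, 1), az0) %*% bend_dir
    trunk <- quadratic_polyline(c(0, 0, 0), c(0, 0, 1), spec$trunk_length,
                                spec$curvature * as.vector(bend_dir))
    comps <- list(list(points = trunk, radius = spec$radius_trunk,
                       kind = "trunk"))
    nb <- spec$n_branches
    if (nb > 0) {
      fracs <- sort(stats::runif(nb, 0.25, 0.9))
      azs <- numeric(nb)
      for (i in seq_len(nb)) {
        az <- stats::runif(1, 0, 2 * pi)
        tries <- 0L
        while (i > 1 && any(abs(fracs[i] - fracs[seq_len(i - 1)]) < 0.12 &
                            abs(az - azs[seq_len(i - 1)]) %% (2 * pi) < 0.6) &&
               tries < 20L) {
          az <- stats::runif(1, 0, 2 * pi)
          tries <- tries + 1L
        }
        if (tries == 20L)
          warning("branch azimuth separation not achieved after retries")
        azs[i] <- az
      }
      s <- c(0, cumsum(sqrt(rowSums(diff(trunk)^2))))
      for (i in seq_len(nb)) {
        si <- fracs[i] * s[length(s)]
        j <- findInterval(si, s, all.inside = TRUE)
        at <- trunk[j, ] + (trunk[j + 1, ] - trunk[j, ]) *
          (si - s[j]) / max(s[j + 1] - s[j], 1e-12)
        tangent <- trunk[j + 1, ] - trunk[j, ]
        tangent <- tangent / sqrt(sum(tangent^2))
        perp <- rotation_axis_angle(tangent, azs[i]) %*% unit_perp(tangent)
        ang <- stats::runif(1, spec$branch_angle_range[1],
                            spec$branch_angle_range[2]) * pi / 180
        dir <- cos(ang) * tangent + sin(ang) * as.vector(perp)
        len <- stats::runif(1, spec$branch_length_range[1],
                            spec$branch_length_range[2])
        bend <- (spec$curvature / 2) * as.vector(
          rotation_axis_angle(dir, stats::runif(1, 0, 2 * pi)) %*%
            unit_perp(dir))
        comps[[length(comps) + 1L]] <- list(
          points = quadratic_polyline(at, dir, len, bend),
          radius = spec$radius_branch, kind = "branch")
      }
    }
    structure(comps, class = "vessel_tree")
  })
}

#' Centreline polylines of a vessel tree
#' @param tree a `vessel_tree`.
#' @return List of polyline matrices (the ground-truth oracle for skeleton
#'   and feature accuracy).
#' @export
tree_centerlines <- function(tree) lapply(tree, `[[`, "points")

#' Rendering profile of an imaging source
#'
#' Describes how one imaging source samples the vessel surface: CT-like
#' renders are denser and cleaner; US-like renders are sparser, noisier,
#' have random dropout, and may be limited to a coverage cone (emulating the
#' limited scanning range of an ultrasound sweep).
#'
#' @param kind `"ct_like"` or `"us_like"`.
#' @param surface_density surface samples per mm^2.
#' @param noise_sigma isotropic Gaussian noise in mm.
#' @param dropout_fraction fraction of points removed at random, in `[0, 1)`.
#' @param coverage_cone optional list with `apex` (3-vector), `axis` (unit
#'   3-vector) and `half_angle` (degrees); points outside the cone are
#'   removed.
#' @return A list of class `source_profile`.
#' @export
source_profile <- function(kind = c("ct_like", "us_like"),
                           surface_density = NULL, noise_sigma = NULL,
                           dropout_fraction = NULL, coverage_cone = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "ct_like") list(d = 0.7, s = 0.2, f = 0)
         else list(d = 0.45, s = 0.35, f = 0.3)
  surface_density <- surface_density %||% def$d
  noise_sigma <- noise_sigma %||% def$s
  dropout_fraction <- dropout_fraction %||% def$f
  if (surface_density <= 0) stop("surface_density must be positive")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must lie in [0, 1)")
  structure(list(kind = kind, surface_density = surface_density,
                 noise_sigma = noise_sigma,
                 dropout_fraction = dropout_fraction,
                 coverage_cone = coverage_cone),
            class = "source_profile")
}

# interpolate centre and tangent of a polyline at arc lengths u
polyline_at <- function(P, u) {
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  j <- findInterval(u, s, all.inside = TRUE)
  seg <- P[j + 1, , drop = FALSE] - P[j, , drop = FALSE]
  segl <- sqrt(rowSums(seg^2))
  tang <- seg / pmax(segl, 1e-12)
  frac <- (u - s[j]) / pmax(s[j + 1] - s[j], 1e-12)
  list(center = P[j, , drop = FALSE] + seg * frac, tangent = tang)
}

#' Render a vessel tree as a source-specific point cloud
#'
#' Samples each component's tube surface at the profile's density, adds
#' isotropic Gaussian noise, removes a seeded dropout fraction, and removes
#' points outside the coverage cone when one is set.
#'
#' @param tree a `vessel_tree`.
#' @param profile a [source_profile].
#' @param seed integer seed; the render is deterministic per seed.
#' @return A [point_cloud] labelled with the profile kind.
#' @export
render_cloud <- function(tree, profile, seed = 0) {
  with_preserved_rng(seed, {
    parts <- lapply(tree, function(comp) {
      P <- comp$points
      r <- comp$radius
      total <- sum(sqrt(rowSums(diff(P)^2)))
      n <- round(profile$surface_density * 2 * pi * r * total)
      if (n < 1) return(NULL)
      u <- stats::runif(n, 0, total)
      th <- stats::runif(n, 0, 2 * pi)
      at <- polyline_at(P, u)
      # per-point frame perpendicular to the tangent
      n1 <- t(apply(at$tangent, 1, unit_perp))
      n2 <- cbind(at$tangent[, 2] * n1[, 3] - at$tangent[, 3] * n1[, 2],
                  at$tangent[, 3] * n1[, 1] - at$tangent[, 1] * n1[, 3],
                  at$tangent[, 1] * n1[, 2] - at$tangent[, 2] * n1[, 1])
      at$center + r * (cos(th) * n1 + sin(th) * n2)
    })
    pts <- do.call(rbind, parts)
    if (profile$noise_sigma > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, profile$noise_sigma),
                          nrow(pts), 3)
    if (profile$dropout_fraction > 0)
      pts <- pts[stats::runif(nrow(pts)) >= profile$dropout_fraction, ,
                 drop = FALSE]
    cone <- profile$coverage_cone
    if (!is.null(cone)) {
      rel <- sweep(pts, 2, cone$apex)
      ct <- as.vector(rel %*% (cone$axis / sqrt(sum(cone$axis^2)))) /
        pmax(sqrt(rowSums(rel^2)), 1e-12)
      pts <- pts[ct >= cos(cone$half_angle * pi / 180), , drop = FALSE]
      if (nrow(pts) == 0)
        stop("coverage cone removed every point; widen the cone")
    }
    point_cloud(pts, label = sub("_like$", "", profile$kind))
  })
}

#' Sample a random rigid transform
#'
#' Rotation: uniform axis, angle uniform in `[0, max_rotation]`; translation
#' uniform in the ball of radius `max_translation`.
#'
#' @param max_rotation degrees.
#' @param max_translation mm.
#' @param seed integer seed.
#' @return A [rigid_transform].
#' @export
random_rigid_transform <- function(max_rotation = 30, max_translation = 20,
                                   seed = 0) {
  with_preserved_rng(seed, {
    ang <- stats::runif(1, 0, max_rotation) * pi / 180
    R <- rotation_axis_angle(random_unit_vector(), ang)
    t <- random_unit_vector() * max_translation * stats::runif(1)^(1 / 3)
    if (max_translation == 0) t <- c(0, 0, 0)
    if (max_rotation == 0) R <- diag(3)
    rigid_transform(R, t)
  })
}

#' Build a synthetic cross-source evaluation case
#'
#' Renders the fixed US-like cloud in the canonical frame, samples a seeded
#' ground-truth rigid transform within the magnitude bounds and applies its
#' inverse to the CT-like render (so the ground truth maps moving onto
#' fixed), and places spherical tumour markers near the vessels with centres
#' recorded in both frames.  When the US profile has `coverage_cone =
#' "auto"`, a cone is fitted from a seeded viewpoint so that roughly 85% of
#' the US render survives, emulating the limited scanning range of the
#' probe.
#'
#' @param spec a [vessel_tree_spec].
#' @param ct_profile,us_profile [source_profile] objects.
#' @param transform_magnitude `c(max_rotation_deg, max_translation_mm)`.
#' @param n_tumors number of spherical tumours (default 4).
#' @param seed integer master seed; independent per-stage streams are
#'   derived from it.
#' @return An object of class `eval_case`: list with `fixed`, `moving`
#'   ([point_cloud]s), `tumor_centers_fixed`, `tumor_centers_moving`,
#'   `tumor_radii`, `tumor_masks` (per-tumour voxel volumes with `origin`
#'   and `spacing`), `ground_truth` ([rigid_transform]), `centerlines`
#'   (fixed-frame polylines, the oracle) and `tree`.
#' @export
make_case <- function(spec,
                      ct_profile = source_profile("ct_like"),
                      us_profile = source_profile("us_like"),
                      transform_magnitude = c(30, 20), n_tumors = 4,
                      seed = 0) {
  seeds <- derive_seeds(seed, 5)
  tree <- generate_vessel_tree(
    vessel_tree_spec(spec$n_branches, spec$trunk_length,
                     spec$branch_length_range, spec$branch_angle_range,
                     spec$radius_trunk, spec$radius_branch, spec$curvature,
                     seed = seeds[1]))
  if (identical(us_profile$coverage_cone, "auto")) {
    us_profile$coverage_cone <- auto_cone(tree, keep = 0.85, seed = seeds[5])
  }
  fixed <- render_cloud(tree, us_profile, seed = seeds[2])
  ct <- render_cloud(tree, ct_profile, seed = seeds[3])
  T_gt <- random_rigid_transform(transform_magnitude[1],
                                 transform_magnitude[2], seed = seeds[4])
  moving <- apply_transform(ct, invert_transform(T_gt))

  centers_fixed <- NULL; centers_moving <- NULL; radii <- NULL; masks <- NULL
  if (n_tumors > 0) {
    with_preserved_rng(seeds[4] + 1L, {
      centers_fixed <- t(vapply(seq_len(n_tumors), function(i) {
        comp <- tree[[sample.int(length(tree), 1)]]
        at <- comp$points[sample.int(nrow(comp$points), 1), ]
        at + random_unit_vector() * stats::runif(1, 10, 25)
      }, numeric(3)))
      radii <- stats::runif(n_tumors, 6, 10)
    })
    centers_moving <- transform_points(centers_fixed, invert_transform(T_gt))
    masks <- lapply(seq_len(n_tumors), function(i) {
      lo <- centers_fixed[i, ] - radii[i] - 2
      dims <- as.integer(ceiling(rep(2 * radii[i] + 4, 3))) + 1L
      list(mask = voxelize_spheres(centers_fixed[i, , drop = FALSE],
                                   radii[i], lo, 1, dims),
           origin = lo, spacing = 1)
    })
  }
  structure(list(fixed = fixed, moving = moving,
                 tumor_centers_fixed = centers_fixed,
                 tumor_centers_moving = centers_moving,
                 tumor_radii = radii, tumor_masks = masks,
                 ground_truth = T_gt,
                 centerlines = tree_centerlines(tree), tree = tree),
            class = "eval_case")
}

# fit a coverage cone from a seeded viewpoint keeping ~`keep` of the tree
auto_cone <- function(tree, keep = 0.85, seed = 0) {
  pts <- do.call(rbind, tree_centerlines(tree))
  ctr <- colMeans(pts)
  with_preserved_rng(seed, {
    dir <- random_unit_vector()
  })
  apex <- ctr - 250 * dir
  rel <- sweep(pts, 2, apex)
  ct <- as.vector(rel %*% dir) / sqrt(rowSums(rel^2))
  ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  half <- as.numeric(stats::quantile(ang, keep)) + 1  # +1 deg tube margin
  list(apex = apex, axis = dir, half_angle = half)
}

# derive independent per-stage seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 65011L) * 33013L + 7919L * seq_len(n)
}

#' @export
print.eval_case <- function(x, ...) {
  cat(sprintf("eval_case: fixed %d pts (%s), moving %d pts (%s), %d tumours\n",
              nrow(x$fixed$points), x$fixed$label %||% "?",
              nrow(x$moving$points), x$moving$label %||% "?",
              if (is.null(x$tumor_radii)) 0L else length(x$tumor_radii)))
  invisible(x)
}
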