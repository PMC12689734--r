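test_that("segments are ordered along their principal direction", {
  P <- cbind(seq(0, 30, length.out = 12), 0.1 * sin(1:12), 0)
  o <- order_segment(P)
  expect_equal(o$order, 1:12)
  expect_equal(abs(o$axis[1]), 1, tolerance = 1e-4)

  # permutation invariance: reversed input gives the same ordered points
  o2 <- order_segment(P[12:1, ])
  expect_equal(o2$points[order(o2$points[, 1]), ],
               o$points[order(o$points[, 1]), ])

  # gentle helix: ordering equals the generator's arc-length parameter
  t <- seq(0, 1, length.out = 40)
  H <- cbind(2 * cos(6 * t), 2 * sin(6 * t), 80 * t)  # pitch >> radius
  set.seed(8)
  perm <- sample(40)
  o3 <- order_segment(H[perm, ])
  expect_equal(o3$points, H)

  expect_error(order_segment(matrix(1, 4, 3)), "zero-variance")
})

test_that("vessel points are claimed uniquely by their nearest skeleton point", {
  # 15 mm radius boundary: closed inclusion
  sk <- matrix(c(0, 0, 0), 1)
  orig <- rbind(c(14, 0, 0), c(16, 0, 0), c(15, 0, 0))
  sets <- assign_vessel_points(orig, sk, assign_radius = 15)
  expect_equal(sets[[1]], c(1L, 3L))

  # one original point near two skeleton points appears in exactly one set
  sk2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  sets2 <- assign_vessel_points(matrix(c(0.4, 0, 0), 1), sk2, 15)
  expect_equal(lengths(sets2), c(1L, 0L))

  # seeded tube: the union of the sets equals the exhaustive scan oracle
  P <- cylinder_cloud(500, r = 3, len = 60, seed = 6)
  skel <- cbind(0, 0, seq(5, 55, by = 2))
  sets3 <- assign_vessel_points(P, skel, 15)
  got <- sort(unlist(sets3))
  D <- sqrt(outer(rowSums(P^2), rowSums(skel^2), `+`) -
            2 * P %*% t(skel))
  expect_equal(got, which(apply(D, 1, min) <= 15))
  expect_equal(anyDuplicated(got), 0)
})

test_that("centre refinement is exact on symmetric cross-sections", {
  # perfect ring, centre on the axis: A/B antipodal, d = diameter, C' = C
  P <- ring_points(36, r = 5)
  out <- refine_center(P, C = c(0, 0, 0), axis = c(0, 0, 1))
  expect_equal(out$d, 10, tolerance = 1e-6)
  expect_equal(sum(out$A * out$B) / (5 * 5), -1, tolerance = 1e-3)
  expect_equal(as.vector(out$C_prime), c(0, 0, 0), tolerance = 1e-9)

  # any point set symmetric about C keeps C' = C
  set.seed(10)
  H <- matrix(rnorm(60), ncol = 3)
  Psym <- rbind(H, -H)
  out2 <- refine_center(Psym, C = c(0, 0, 0))
  expect_equal(as.vector(out2$C_prime), c(0, 0, 0), tolerance = 1e-9)

  # the refined centre never leaves the bounding box of P
  for (s in 1:20) {
    set.seed(s)
    Q <- matrix(runif(45, -10, 10), ncol = 3)
    o <- refine_center(Q, colMeans(Q))
    expect_true(all(o$C_prime >= apply(Q, 2, min) - 1e-12))
    expect_true(all(o$C_prime <= apply(Q, 2, max) + 1e-12))
  }

  # degenerate inputs fall back to C
  expect_true(refine_center(matrix(0, 2, 3), c(1, 1, 1))$degenerate)
  coll <- cbind(1:5, 0, 0)
  expect_true(refine_center(coll, colMeans(coll))$degenerate)
})

test_that("quadratic curve fitting reproduces its own model family", {
  t <- seq(0, 1, length.out = 20)
  X <- cbind(t, t^2, 0)
  cv <- fit_feature_curve(X, curve_samples = 20, axis = c(1, 0, 0))
  expect_lt(max(abs(cv$samples - X)), 1e-9)

  # collinear centres give a straight line (no quadratic term)
  L <- cbind(3 * t, 4 * t, 0)
  cvl <- fit_feature_curve(L, curve_samples = 10)
  expect_lt(max(abs(cvl$coefficients[3, ])), 1e-9)

  # noisy quadratic: coefficients match the normal-equations oracle
  set.seed(15)
  Y <- cbind(t, 5 * t^2 - 2 * t, 1 + t) + matrix(rnorm(60, 0, 0.2), 20, 3)
  ax <- c(1, 0, 0)
  cv2 <- fit_feature_curve(Y, curve_samples = 5, axis = ax)
  tr <- as.vector(Y %*% ax); tn <- (tr - min(tr)) / diff(range(tr))
  D <- cbind(1, tn, tn^2)
  oracle <- solve(crossprod(D), crossprod(D, Y))
  expect_lt(max(abs(cv2$coefficients - oracle)), 1e-9)

  expect_warning(fit_feature_curve(X[1:2, ]), "fewer than 3")
})

test_that("end down-sampling thins branch curves only", {
  mk <- function(kind, n = 20) {
    structure(list(samples = cbind(seq_len(n), 0, 0), weight = 1,
                   segment_kind = kind), class = "feature_curve")
  }
  out <- downsample_ends(list(mk("branch"), mk("trunk")), 5)
  expect_equal(nrow(out[[1]]$samples), 5)
  expect_equal(out[[1]]$samples[, 1], c(1, 6, 11, 16, 20))
  expect_equal(nrow(out[[2]]$samples), 20)
  same <- downsample_ends(list(mk("branch")), 1)
  expect_equal(nrow(same[[1]]$samples), 20)
})

test_that("feature extraction recovers the centreline of synthetic trees", {
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 3, seed = 41))
  pc <- render_cloud(tree, source_profile("ct_like", noise_sigma = 0.1),
                     seed = 41)
  curves <- extract_features(pc, contraction_params(),
                             segmentation_params())
  expect_gte(length(curves), 3)
  cl <- do.call(rbind, tree_centerlines(tree))
  S <- flatten_curves(curves)
  d <- sqrt(skelreg:::cpp_nn(S, cl)$dist2)
  expect_lt(mean(d), 2)
  # the feature set is orders smaller than the input
  expect_lt(nrow(S), nrow(pc$points) / 10)

  # identical inputs give identical outputs (determinism)
  curves2 <- extract_features(pc, contraction_params(),
                              segmentation_params())
  expect_identical(lapply(curves, `[[`, "samples"),
                   lapply(curves2, `[[`, "samples"))
})

test_that("a straight tube yields a single nearly straight curve", {
  pc <- point_cloud(cylinder_cloud(2500, r = 3, len = 90, seed = 44,
                                   sigma = 0.1))
  curves <- extract_features(pc, contraction_params(),
                             segmentation_params())
  expect_length(curves, 1)
  S <- curves[[1]]$samples
  # deviation from the chord between the curve ends
  a <- S[1, ]; b <- S[nrow(S), ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  rel <- sweep(S, 2, a)
  off <- rel - outer(as.vector(rel %*% u), u)
  expect_lt(max(sqrt(rowSums(off^2))), 0.5)
})

test_that("feature extraction is rigid-equivariant at curve level", {
  # with the voxel lattice disabled the whole pipeline commutes with
  # isometries (identical neighbourhoods); the lattice itself is the one
  # rotation-anisotropic stage
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 3, seed = 46))
  pc <- render_cloud(tree, source_profile("ct_like", noise_sigma = 0.1),
                     seed = 46)
  T1 <- rigid_transform(random_rotation(46), c(20, -12, 7))
  cpar <- contraction_params(voxel_edge = NA)
  a <- flatten_curves(extract_features(pc, cpar, segmentation_params()))
  b <- flatten_curves(extract_features(apply_transform(pc, T1), cpar,
                                       segmentation_params()))
  aT <- skelreg:::transform_points(a, T1)
  d1 <- sqrt(skelreg:::cpp_nn(aT, b)$dist2)
  d2 <- sqrt(skelreg:::cpp_nn(b, aT)$dist2)
  expect_lt((mean(d1) + mean(d2)) / 2, 0.5)
})

test_that("human profile weights curves by length and thins branch ends", {
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 3, seed = 47))
  pc <- render_cloud(tree, source_profile("ct_like", noise_sigma = 0.1),
                     seed = 47)
  hp <- extract_features(pc, contraction_params(w_attract0 = 10),
                         segmentation_params(), profile = "human")
  w <- vapply(hp, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))
  nb <- vapply(hp, function(cv) nrow(cv$samples), integer(1))
  kinds <- vapply(hp, `[[`, character(1), "segment_kind")
  if (any(kinds == "branch")) expect_true(all(nb[kinds == "branch"] <= 7))
})
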