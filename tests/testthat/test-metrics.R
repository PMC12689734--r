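test_that("skeleton RMSE matches analytic and brute-force values", {
  L <- cbind(seq(0, 100, by = 0.5), 0, 0)
  expect_equal(skeleton_rmse(L, L), 0)

  # a transverse 3 mm offset of a dense straight line gives RMSE ~ 3
  L2 <- sweep(L, 2, c(0, 3, 0), `+`)
  expect_equal(skeleton_rmse(L, L2), 3, tolerance = 1e-9)

  # brute-force O(N M) oracle on seeded inputs
  set.seed(51)
  A <- matrix(runif(90, 0, 20), ncol = 3)
  B <- matrix(runif(120, 0, 20), ncol = 3)
  T1 <- rigid_transform(random_rotation(51), c(1, -2, 3))
  At <- skelreg:::transform_points(A, T1)
  D2 <- outer(rowSums(At^2), rowSums(B^2), `+`) - 2 * At %*% t(B)
  expect_equal(skeleton_rmse(A, B, T1), sqrt(mean(apply(D2, 1, min))),
               tolerance = 1e-9)
})

test_that("target registration error is the transformed-centre distance", {
  expect_equal(target_registration_error(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(target_registration_error(c(0, 0, 0), c(3, 4, 0)), 5)
  # under the ground-truth transform of a seeded case the TRE vanishes
  T1 <- rigid_transform(random_rotation(52), c(5, 6, -7))
  cm <- c(10, -4, 2)
  cf <- as.vector(T1$R %*% cm) + T1$t
  expect_equal(target_registration_error(cm, cf, T1), 0, tolerance = 1e-9)
})

test_that("Dice and volume similarity match voxel brute force", {
  a <- array(FALSE, c(10, 10, 10)); a[1:6, , ] <- TRUE
  expect_equal(dice_and_vs(a, a), list(dice = 1, volume_similarity = 1))

  # two equal cubes overlapping exactly half their volume
  b <- array(FALSE, c(10, 10, 10)); b[4:9, , ] <- TRUE
  dv <- dice_and_vs(a, b)
  expect_equal(dv$dice, 0.5)
  expect_equal(dv$volume_similarity, 1.0)

  # disjoint masks
  c1 <- array(FALSE, c(4, 4, 4)); c1[1, 1, 1] <- TRUE
  c2 <- array(FALSE, c(4, 4, 4)); c2[4, 4, 4] <- TRUE
  expect_equal(dice_and_vs(c1, c2)$dice, 0)

  # symmetry and the VS = 1 equal-volume property
  expect_equal(dice_and_vs(a, b), dice_and_vs(b, a))
  empty <- array(FALSE, c(4, 4, 4))
  expect_true(is.na(dice_and_vs(empty, empty)$dice))
})

test_that("surface Dice at tolerance matches analytic plane cases", {
  g <- as.matrix(expand.grid(seq(0, 20, by = 1), seq(0, 20, by = 1)))
  plane0 <- cbind(g, 0)
  plane4 <- cbind(g, 4)
  plane6 <- cbind(g, 6)
  expect_equal(surface_dice(plane0, plane0, 5), 1)
  expect_equal(surface_dice(plane0, plane4, 5), 1)
  expect_equal(surface_dice(plane0, plane6, 5), 0)

  # brute-force bidirectional oracle on seeded spheres
  A <- sphere_surface_points(matrix(c(0, 0, 0), 1), 10, 150)
  B <- sphere_surface_points(matrix(c(4, 0, 0), 1), 9, 180)
  tau <- 3
  DA <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  hits <- sum(apply(DA, 1, min) <= tau^2) + sum(apply(DA, 2, min) <= tau^2)
  expect_equal(surface_dice(A, B, tau), hits / (nrow(A) + nrow(B)),
               tolerance = 1e-12)

  # monotone non-decreasing in tau
  taus <- c(0.5, 1, 2, 4, 8)
  vals <- vapply(taus, function(t) surface_dice(A, B, t), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("point metrics are invariant under a common rigid transform", {
  set.seed(53)
  A <- matrix(runif(60, 0, 30), ncol = 3)
  B <- matrix(runif(90, 0, 30), ncol = 3)
  T1 <- rigid_transform(random_rotation(53), c(4, 5, 6))
  At <- skelreg:::transform_points(A, T1)
  Bt <- skelreg:::transform_points(B, T1)
  expect_equal(skeleton_rmse(A, B), skeleton_rmse(At, Bt), tolerance = 1e-9)
  expect_equal(surface_dice(A, B, 3), surface_dice(At, Bt, 3))
  expect_equal(trimmed_residual(A, B, trim_fraction = 0.1),
               trimmed_residual(At, Bt, trim_fraction = 0.1),
               tolerance = 1e-9)
})

test_that("sphere voxelization counts match the analytic volume", {
  r <- 6
  mask <- voxelize_spheres(matrix(c(0, 0, 0), 1), r,
                           origin = c(-8, -8, -8), spacing = 1,
                           dims = c(17, 17, 17))
  vol <- sum(mask)
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
})
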