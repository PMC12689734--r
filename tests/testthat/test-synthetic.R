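test_that("tree generation is deterministic and has the right topology", {
  spec <- vessel_tree_spec(n_branches = 3, seed = 5)
  t1 <- generate_vessel_tree(spec)
  t2 <- generate_vessel_tree(spec)
  expect_identical(t1, t2)

  # trunk length within 1% when no branches are requested
  t0 <- generate_vessel_tree(vessel_tree_spec(n_branches = 0, seed = 2))
  expect_length(t0, 1)
  trunk_len <- sum(sqrt(rowSums(diff(t0[[1]]$points)^2)))
  expect_lt(abs(trunk_len - 150) / 150, 0.01)

  # 3 branches: 4 leaf tips, junctions on the trunk
  expect_length(t1, 4)
  expect_equal(vapply(t1, `[[`, character(1), "kind"),
               c("trunk", "branch", "branch", "branch"))
  # each branch starts on the trunk
  cl <- t1[[1]]$points
  for (b in t1[-1]) {
    d0 <- min(sqrt(skelreg:::cpp_nn(b$points[1, , drop = FALSE], cl)$dist2))
    expect_lt(d0, 1.5)
  }
})

test_that("rendering respects density, noise, dropout and the cone", {
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 2, seed = 9))
  # noise-free, no dropout: every point lies exactly on a tube surface
  clean <- render_cloud(tree, source_profile("ct_like", noise_sigma = 0,
                                             surface_density = 0.3),
                        seed = 9)
  dmin <- rep(Inf, nrow(clean$points))
  for (comp in tree) {
    d <- sqrt(skelreg:::cpp_nn(clean$points, comp$points)$dist2)
    onthis <- abs(d - comp$radius)
    dmin <- pmin(dmin, onthis)
  }
  # polyline discretization (1 mm steps) bounds the deviation
  expect_lt(max(dmin), 0.15)

  # dropout: retained count within the 3-sigma binomial band
  full <- render_cloud(tree, source_profile("ct_like", dropout_fraction = 0,
                                            surface_density = 0.7), seed = 4)
  n0 <- nrow(full$points)
  drop <- render_cloud(tree, source_profile("ct_like", dropout_fraction = 0.3,
                                            surface_density = 0.7), seed = 4)
  expected <- 0.7 * n0
  band <- 3 * sqrt(n0 * 0.3 * 0.7)
  expect_lt(abs(nrow(drop$points) - expected), band)

  # density ratio carries through to the counts within 5%
  lo <- render_cloud(tree, source_profile("ct_like", surface_density = 0.35,
                                          noise_sigma = 0), seed = 11)
  hi <- render_cloud(tree, source_profile("ct_like", surface_density = 0.7,
                                          noise_sigma = 0), seed = 11)
  expect_lt(abs(nrow(hi$points) / nrow(lo$points) - 2), 0.1)

  # an over-tight cone errors out
  expect_error(render_cloud(tree, source_profile("us_like",
    coverage_cone = list(apex = c(0, 0, -500), axis = c(0, 0, -1),
                         half_angle = 5)), seed = 2), "cone")
})

test_that("cases carry exact ground-truth bookkeeping", {
  case <- make_case(vessel_tree_spec(n_branches = 3, seed = 13),
                    us_profile = source_profile("us_like",
                                                coverage_cone = "auto"),
                    n_tumors = 4, seed = 13)
  gt <- case$ground_truth
  # centre bookkeeping: fixed = T_gt * moving exactly
  lhs <- skelreg:::transform_points(case$tumor_centers_moving, gt)
  expect_equal(lhs, case$tumor_centers_fixed, tolerance = 1e-9)

  # zero-magnitude transform: ground truth is the identity
  c0 <- make_case(vessel_tree_spec(n_branches = 2, seed = 14),
                  transform_magnitude = c(0, 0), n_tumors = 1, seed = 14)
  expect_equal(c0$ground_truth$R, diag(3))
  expect_equal(c0$ground_truth$t, c(0, 0, 0))

  # reproducibility: same seed, bit-identical case
  case2 <- make_case(vessel_tree_spec(n_branches = 3, seed = 13),
                     us_profile = source_profile("us_like",
                                                 coverage_cone = "auto"),
                     n_tumors = 4, seed = 13)
  expect_identical(case$fixed$points, case2$fixed$points)
  expect_identical(case$moving$points, case2$moving$points)
  expect_identical(case$ground_truth, case2$ground_truth)

  # masks voxelize the recorded spheres on a 1 mm grid
  m <- case$tumor_masks[[1]]
  expect_equal(m$spacing, 1)
  expect_gt(sum(m$mask), 0)

  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_case(vessel_tree_spec(seed = 1), seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("sampled rigid transforms respect their magnitude bounds", {
  for (s in 1:20) {
    T1 <- random_rigid_transform(30, 20, seed = s)
    expect_lte(skelreg:::rotation_angle(T1$R) * 180 / pi, 30 + 1e-9)
    expect_lte(sqrt(sum(T1$t^2)), 20 + 1e-9)
  }
})
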