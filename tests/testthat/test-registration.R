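test_that("pair normalization centres, scales and round-trips exactly", {
  set.seed(31)
  A <- matrix(runif(90, 0, 200), ncol = 3)
  B <- matrix(runif(60, 0, 200), ncol = 3)
  np <- normalize_pair(A, B)
  joint <- rbind(np$source, np$target)
  expect_lt(max(apply(joint, 2, function(v) diff(range(v)))), 1 + 1e-12)
  # scale factor equals 1 / largest joint extent
  span <- max(apply(rbind(A, B), 2, function(v) diff(range(v))))
  expect_equal(np$scale, 1 / span)

  # identical clouds map to identical normalized clouds
  np2 <- normalize_pair(A, A)
  expect_equal(np2$source, np2$target)

  # denormalizing the identity gives the identity in mm space
  Tid <- np$denormalize(rigid_transform())
  expect_equal(Tid$R, diag(3))
  expect_equal(Tid$t, c(0, 0, 0), tolerance = 1e-9)

  # a normalized-space transform maps back exactly
  Tn <- rigid_transform(random_rotation(3), c(0.1, -0.2, 0.05))
  Tmm <- np$denormalize(Tn)
  norm_fun <- function(X) sweep(X, 2, np$center) * np$scale
  lhs <- norm_fun(skelreg:::transform_points(A, Tmm))
  rhs <- skelreg:::transform_points(norm_fun(A), Tn)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  expect_error(normalize_pair(matrix(1, 3, 3), matrix(1, 2, 3)),
               "zero-extent")
})

test_that("the trimmed residual matches brute-force computation", {
  set.seed(32)
  A <- matrix(runif(60, 0, 10), ncol = 3)
  expect_equal(trimmed_residual(A, A, rigid_transform(), 0.1), 0)

  # one gross outlier is excluded at trim 0.1
  B <- A[1:10, ]
  Bout <- rbind(B[1:9, ], c(1000, 0, 0))
  d2 <- rowSums((B[1:9, ] - Bout[1:9, ])^2)   # zeros
  r <- trimmed_residual(Bout, B, rigid_transform(), 0.1)
  D <- as.matrix(dist(rbind(Bout, B)))[1:10, 11:20]
  nn2 <- apply(D, 1, min)^2
  expect_equal(r, mean(sort(nn2)[1:9]))
  expect_lt(r, 1)

  # trim 0 equals the plain mean against an O(N M) scan oracle
  C <- matrix(runif(45, 0, 10), ncol = 3)
  T1 <- rigid_transform(random_rotation(5), c(1, 2, 3))
  r0 <- trimmed_residual(A, C, T1, 0)
  At <- skelreg:::transform_points(A, T1)
  D2 <- outer(rowSums(At^2), rowSums(C^2), `+`) - 2 * At %*% t(C)
  expect_equal(r0, mean(apply(D2, 1, min)), tolerance = 1e-9)
})

test_that("fine ICP recovers exact displacements and honours its caps", {
  set.seed(33)
  A <- matrix(runif(150, 0, 50), ncol = 3)
  # source = target: immediate convergence
  res <- icp_fine(A, A)
  expect_equal(res$rmse, 0, tolerance = 1e-12)
  expect_lte(res$iterations, 1)
  expect_true(res$converged)

  # pure 2 mm translation: recovered to closed-form accuracy
  B <- sweep(A, 2, c(2, 0, 0), `+`)
  res2 <- icp_fine(A, B)
  expect_equal(res2$transform$t, c(2, 0, 0), tolerance = 1e-6)
  expect_equal(res2$transform$R, diag(3), tolerance = 1e-9)

  # iteration cap is honoured even for an adversarial pair
  set.seed(34)
  C2 <- matrix(runif(150, 0, 50), ncol = 3)
  res3 <- icp_fine(A, C2, init = rigid_transform(random_rotation(7),
                                                 c(10, -8, 5)))
  expect_lte(res3$iterations, 20)
  # residual trace is non-increasing
  expect_true(all(diff(res3$stage_trace$icp_rms) <= 1e-12))

  expect_error(icp_fine(A[1:4, ], matrix(c(0, 0, 0), 1)), "degenerate")
})

test_that("coarse branch-and-bound recovers a 40-degree pose", {
  # 60 curve-structured feature points from a synthetic vessel tree
  tree <- generate_vessel_tree(vessel_tree_spec(n_branches = 2, seed = 35))
  cl <- do.call(rbind, tree_centerlines(tree))
  set.seed(35)
  S <- cl[sort(sample.int(nrow(cl), 60)), ]
  T_gt <- rigid_transform(rotation_axis_angle(c(1, 2, -1), 40 * pi / 180),
                          c(12, -9, 14))
  Tg <- skelreg:::transform_points(S, T_gt)
  res <- goicp_coarse(S, Tg, goicp_params(max_bnb_expansions = 20000))
  expect_true(res$converged)
  err_R <- skelreg:::rotation_angle(t(T_gt$R) %*% res$transform$R) * 180 / pi
  expect_lt(err_R, 1)
  expect_lt(sqrt(sum((res$transform$t - T_gt$t)^2)), 0.5)
  expect_lte(res$stage_trace$goicp_trimmed_mse, 0.001)

  # source = target: identity within numerical tolerance
  res0 <- goicp_coarse(S, S, goicp_params(max_bnb_expansions = 2000))
  expect_lt(skelreg:::rotation_angle(res0$transform$R) * 180 / pi, 0.5)
  expect_lt(sqrt(sum(res0$transform$t^2)), 0.5)
  expect_lt(res0$rmse, 1e-3)

  # invariance to the order of the source points (set semantics)
  perm <- sample(nrow(S))
  resp <- goicp_coarse(S[perm, ], Tg,
                       goicp_params(max_bnb_expansions = 20000))
  expect_equal(resp$transform$R, res$transform$R, tolerance = 1e-6)
  expect_equal(resp$transform$t, res$transform$t, tolerance = 1e-6)
})

test_that("all returned transforms satisfy the rigidity invariants", {
  pair <- feature_pair(seed = 61)
  res <- register_features(pair$source, pair$target,
                           goicp_params(max_bnb_expansions = 500))
  R <- res$transform$R
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("two-stage registration recovers synthetic feature poses", {
  for (s in c(71, 72)) {
    pair <- feature_pair(seed = s)
    res <- register_features(pair$source, pair$target,
                             goicp_params(max_bnb_expansions = 500))
    err_R <- skelreg:::rotation_angle(t(pair$T_gt$R) %*% res$transform$R)
    expect_lt(err_R * 180 / pi, 1)
    expect_lt(sqrt(sum((res$transform$t - pair$T_gt$t)^2)), 1)
  }
  # identical curve sets: identity within tolerance, near-zero residual
  pair <- feature_pair(seed = 73)
  res <- register_features(pair$target, pair$target,
                           goicp_params(max_bnb_expansions = 2000))
  expect_lt(res$rmse, 1e-3)
  expect_lt(skelreg:::rotation_angle(res$transform$R) * 180 / pi, 0.5)
})

test_that("registration direction flag inverts the reported transform", {
  case <- cached("case_small", make_case(
    vessel_tree_spec(n_branches = 3, seed = 203),
    us_profile = source_profile("us_like", coverage_cone = "auto"),
    transform_magnitude = c(20, 15), seed = 203))
  cfg1 <- default_config(seed = 203)
  cfg1$goicp$max_bnb_expansions <- 500
  cfg2 <- cfg1
  cfg2$direction <- "us_to_ct"
  out1 <- cached("case_small_reg", register_case(case, cfg1))
  out2 <- register_case(case, cfg2)
  Tinv <- invert_transform(out2$result$transform)
  expect_equal(out1$result$transform$R, Tinv$R, tolerance = 1e-9)
  expect_equal(out1$result$transform$t, Tinv$t, tolerance = 1e-6)
})

test_that("the full case pipeline reaches millimetre tumour accuracy", {
  case <- cached("case_small", make_case(
    vessel_tree_spec(n_branches = 3, seed = 203),
    us_profile = source_profile("us_like", coverage_cone = "auto"),
    transform_magnitude = c(20, 15), seed = 203))
  cfg <- default_config(seed = 203)
  cfg$goicp$max_bnb_expansions <- 500
  out <- cached("case_small_reg", register_case(case, cfg))
  expect_lte(max(out$report$tre_per_tumor), 2)

  # moving = fixed with identity ground truth: TRE ~ 0
  selfcase <- list(fixed = case$fixed, moving = case$fixed,
                   tumor_centers_fixed = case$tumor_centers_fixed,
                   tumor_centers_moving = case$tumor_centers_fixed)
  out2 <- register_case(selfcase, cfg)
  expect_lt(max(out2$report$tre_per_tumor), 0.5)
})
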