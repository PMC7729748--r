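test_that("relative angular velocity is expressed in the proximal frame", {
  expect_equal(relative_angvel(diag(3), diag(3), c(1, 1, 1), c(1, 1, 1)),
               rep(0, 3))
  expect_equal(relative_angvel(diag(3), diag(3), c(0, 0, 1), c(0, 0, 2)),
               c(0, 0, 1))
  Rz <- rot_exp(c(0, 0, pi / 2))
  expect_equal(relative_angvel(Rz, diag(3), c(0, 0, 0), c(1, 0, 0)),
               c(0, -1, 0), tolerance = 1e-12)
})

test_that("hinge residual removes the axis-parallel component", {
  set.seed(20)
  r <- rand_unit()
  # perfect hinge: m parallel to r
  expect_equal(hinge_residual(r, diag(3), rot_exp(1.7 * r), rep(0, 3), 1.7 * r),
               rep(0, 3), tolerance = 1e-12)
  expect_equal(hinge_residual(c(0, 0, 1), diag(3), diag(3),
                              rep(0, 3), c(0.1, 0, 1)), c(0.1, 0, 0))
  # sign symmetry and axis-orthogonality on random draws
  for (i in 1:200) {
    r <- rand_unit()
    RA <- rand_rotation(); RB <- rand_rotation()
    wA <- rnorm(3); wB <- rnorm(3)
    e <- hinge_residual(r, RA, RB, wA, wB)
    expect_equal(e, hinge_residual(-r, RA, RB, wA, wB), tolerance = 1e-14)
    expect_lt(abs(sum(e * r)), 1e-12)
  }
})

test_that("joint-center residual names a common point and is left-invariant", {
  expect_equal(joint_center_residual(pose(), c(0, 0, 1),
                                     pose(p = c(0, 0, 2)), c(0, 0, -1)),
               rep(0, 3))
  expect_equal(joint_center_residual(pose(), c(0, 0, 1), pose(), c(0, 0, 0.9)),
               c(0, 0, 0.1))
  set.seed(21)
  for (i in 1:20) {
    XA <- pose(rand_rotation(), rnorm(3))
    XB <- pose(rand_rotation(), rnorm(3))
    sA <- rnorm(3); sB <- rnorm(3)
    G <- pose(rand_rotation(), rnorm(3))
    e1 <- joint_center_residual(XA, sA, XB, sB)
    e2 <- joint_center_residual(pose_compose(G, XA), sA,
                                pose_compose(G, XB), sB)
    # residual norm (not components) is invariant to a common rigid transform
    expect_equal(sqrt(sum(e1^2)), sqrt(sum(e2^2)), tolerance = 1e-10)
    expect_equal(as.numeric(G$R %*% e1), e2, tolerance = 1e-10)
  }
})

test_that("axis-segment angle residual matches direct substitution", {
  pr <- list(mu = pi / 2, sigma = 0.04)
  expect_equal(axis_segment_angle_residual(c(1, 0, 0), c(0, 0, 0.2),
                                           c(0, 0, -0.2), pr), 0)
  pr84 <- list(mu = 84 * pi / 180, sigma = 2.4 * pi / 180)
  e <- axis_segment_angle_residual(c(1, 0, 0), c(0, 0, 0.4), c(0, 0, 0), pr84)
  expect_equal(e, -6 * pi / 180, tolerance = 1e-12)
  # invariant to positive scaling of the segment vector
  e2 <- axis_segment_angle_residual(c(1, 0, 0), c(0, 0, 4), c(0, 0, 0), pr84)
  expect_equal(e, e2)
  expect_error(axis_segment_angle_residual(c(1, 0, 0), c(1, 1, 1),
                                           c(1, 1, 1), pr84), "zero-length")
})

test_that("segment-length residual measures joint-center separation", {
  pr <- list(mu = 0.394, sigma = 0.03)
  expect_equal(segment_length_residual(c(0, 0, 0.394), c(0, 0, 0), pr), 0)
  expect_equal(segment_length_residual(c(0, 0, 0.5), c(0, 0, 0), pr), 0.106)
  set.seed(22)
  R <- rand_rotation()
  s1 <- rnorm(3); s2 <- rnorm(3)
  expect_equal(segment_length_residual(as.numeric(R %*% s1),
                                       as.numeric(R %*% s2), pr),
               segment_length_residual(s1, s2, pr), tolerance = 1e-12)
})

test_that("length window penalty is zero inside, tanh-shaped outside", {
  fem <- list(lmin = 0.326, lmax = 0.480, a = 100)
  expect_equal(length_window_penalty(0.40, fem), 0)
  expect_equal(length_window_penalty(0.480, fem), 0)
  expect_equal(length_window_penalty(0.500, fem), 0.02 * tanh(2)^2,
               tolerance = 1e-12)
  # nonnegative, continuous, monotone in distance outside the window
  xs <- seq(0, 0.8, by = 1e-3)
  ys <- vapply(xs, length_window_penalty, numeric(1), prior = fem)
  expect_true(all(ys >= 0))
  expect_true(all(diff(ys[xs >= fem$lmax]) >= 0))
  expect_true(all(diff(ys[xs <= fem$lmin]) <= 0))
  expect_lt(max(abs(diff(ys))), 2e-3)  # no jumps at the joins
})

test_that("discrepancy residual is the right-minus-left length difference", {
  expect_equal(discrepancy_residual(c(0, 0, 0.2), c(0, 0, -0.2),
                                    c(0, 0.1, 0.2), c(0, 0.1, -0.2)), 0)
  expect_equal(discrepancy_residual(c(0, 0, 0.4), c(0, 0, 0),
                                    c(0, 0, 0.39), c(0, 0, 0)), 0.01)
  set.seed(23)
  a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3); d <- rnorm(3)
  expect_equal(discrepancy_residual(a, b, cc, d),
               -discrepancy_residual(cc, d, a, b))
})

test_that("composite population prior averages means, adds variances", {
  p <- compose_population_prior(0.4, 0.03, 0.4, 0.03)
  expect_equal(p$mu, 0.4)
  expect_equal(p$sigma, 0.042426, tolerance = 1e-5)
  expect_equal(compose_population_prior(0.4, 0.03, 0.5, 1e-12)$sigma, 0.03,
               tolerance = 1e-6)
  set.seed(24)
  for (i in 1:10) {
    mM <- runif(1); mF <- runif(1)
    p <- compose_population_prior(mM, 0.1, mF, 0.2)
    expect_true(p$mu >= min(mM, mF) && p$mu <= max(mM, mF))
  }
})

test_that("fit_noise_covariance is the zero-mean ML estimate", {
  expect_warning(S0 <- fit_noise_covariance(matrix(0, 2, 3)), "rank")
  expect_lt(max(abs(S0)), 1e-8)
  set.seed(25)
  X <- cbind(rnorm(1e5, 0, 2), rnorm(1e5), rnorm(1e5))
  S <- fit_noise_covariance(X)
  expect_equal(diag(S), c(4, 1, 1), tolerance = 0.05)
  Sp <- fit_noise_covariance(X[c(2:1e5, 1), ])
  expect_equal(S, Sp, tolerance = 1e-12)
})

test_that("all residual models vanish on noise-free ground truth", {
  tr <- fx_truth()
  offs <- tr$offs_true
  axes <- tr$axes_true
  imus <- tr$imus
  set.seed(26)
  ks <- sample(tr$n, 40)
  jc_map <- list(c(1, 1, 2, 3), c(2, 4, 3, 5), c(3, 6, 4, 7),
                 c(1, 2, 5, 8), c(5, 9, 6, 10), c(6, 11, 7, 12))
  hinge_map <- list(c(1, 2, 3), c(2, 3, 2), c(3, 5, 6), c(4, 6, 5))
  for (k in ks) {
    for (m in jc_map) {
      e <- joint_center_residual(
        pose(imus[[m[1]]]$R[, , k], imus[[m[1]]]$p[, k]), offs[, m[2]],
        pose(imus[[m[3]]]$R[, , k], imus[[m[3]]]$p[, k]), offs[, m[4]])
      expect_lt(max(abs(e)), 1e-10)
    }
    for (m in hinge_map) {
      e <- hinge_residual(axes[, m[1]], imus[[m[2]]]$R[, , k],
                          imus[[m[3]]]$R[, , k], imus[[m[2]]]$w[, k],
                          imus[[m[3]]]$w[, k])
      expect_lt(max(abs(e)), 1e-10)
    }
  }
  # axis-segment angles at truth match the sampled skeleton angles
  th <- tr$skeleton$axis_angles_deg
  prs <- list(list(1, 3, 4, th$fr), list(2, 5, 6, th$tr),
              list(3, 8, 9, th$fl), list(4, 10, 11, th$tl))
  for (p in prs) {
    e <- axis_segment_angle_residual(
      axes[, p[[1]]], offs[, p[[2]]], offs[, p[[3]]],
      list(mu = p[[4]] * pi / 180, sigma = 1))
    expect_lt(abs(e), 1e-10)
  }
  # segment lengths at truth equal the sampled lengths
  expect_equal(segment_length_residual(offs[, 3], offs[, 4],
                                       list(mu = tr$skeleton$femur[["right"]])),
               0, tolerance = 1e-10)
  expect_equal(segment_length_residual(offs[, 10], offs[, 11],
                                       list(mu = tr$skeleton$tibia[["left"]])),
               0, tolerance = 1e-10)
})
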