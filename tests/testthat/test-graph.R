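test_that("graph factor accounting matches the model structure", {
  g <- fx_graph_tiny()
  expect_identical(g$M, 3L)
  expect_identical(g$counts$preintegration, 14L)
  expect_identical(g$counts$bias_walk, 14L)
  expect_identical(g$counts$angular_velocity, 21L)
  expect_identical(g$counts$hinge, 12L)
  expect_identical(g$counts$joint_center, 18L)
  expect_identical(g$counts$axis_segment, 4L)
  expect_identical(g$counts$length, 5L)
  expect_identical(g$counts$window, 5L)
  expect_identical(g$counts$discrepancy, 2L)
  expect_identical(g$dim, 126L * 3L + 44L)

  # M = 300 gives the 126 M + 44 accounting
  st300 <- truncate_streams(fx_streams_clean(), 1 + 299 * 20)
  g300 <- build_graph(st300, fx_noise())
  expect_identical(g300$M, 300L)
  expect_identical(g300$dim, 37844L)
})

test_that("graph construction validates its inputs", {
  st <- fx_streams_clean()
  expect_error(build_graph(st[1:6], fx_noise()), "7 IMU streams")
  st_bad <- st
  st_bad[[3]]$t <- st_bad[[3]]$t + 0.01
  expect_error(build_graph(st_bad, fx_noise()), "misaligned")
  expect_error(build_graph(truncate_streams(st, 30), fx_noise(),
                           decimation = 20), "too short")
})

test_that("total error equals an independent factor-by-factor enumeration", {
  g <- fx_graph_tiny()
  tr <- fx_truth()
  noise <- g$noise
  streams <- truncate_streams(fx_streams_clean(), 41)
  # evaluate at perturbed (non-trivial) values so every factor is nonzero
  vals <- values_from_truth(g, tr)
  set.seed(30)
  delta <- rnorm(g$dim, sd = 0.02)
  vals <- imumocap:::.retract_values(vals, delta)

  state_at <- function(k, s) {
    i <- (k - 1) * 7 + s
    imu_state(vals$R[, , i], vals$p[, i], vals$v[, i], vals$w[, i],
              vals$b[, i])
  }
  err <- 0
  Wg <- solve(t(chol(noise$Sigma_g)))
  WK <- solve(t(chol(noise$Sigma_K)))
  Wj <- solve(t(chol(noise$Sigma_j)))
  for (s in 1:7) {
    for (k in 1:(g$M - 1)) {
      rows <- (1 + (k - 1) * g$decimation):(k * g$decimation)
      d <- preintegrate(streams[[s]]$gyro[rows, ], streams[[s]]$accel[rows, ],
                        noise)
      err <- err + sum(preint_residual(d, state_at(k, s), state_at(k + 1, s),
                                       noise, whiten = TRUE)^2)
      err <- err + sum(bias_residual(state_at(k, s)$b, state_at(k + 1, s)$b,
                                     d$dT, noise, whiten = TRUE)^2)
    }
    for (k in 1:g$M) {
      kf_row <- 1 + (k - 1) * g$decimation
      e <- angvel_residual(state_at(k, s)$w, state_at(k, s)$b[1:3],
                           streams[[s]]$gyro[kf_row, ])
      err <- err + sum((Wg %*% e)^2)
    }
  }
  hinge_map <- list(c(1, 2, 3), c(2, 3, 2), c(3, 5, 6), c(4, 6, 5))
  jc_map <- list(c(1, 1, 2, 3), c(2, 4, 3, 5), c(3, 6, 4, 7),
                 c(1, 2, 5, 8), c(5, 9, 6, 10), c(6, 11, 7, 12))
  for (k in 1:g$M) {
    for (m in hinge_map) {
      A <- state_at(k, m[2]); B <- state_at(k, m[3])
      e <- hinge_residual(vals$axes[, m[1]], A$R, B$R, A$w, B$w)
      err <- err + sum((WK %*% e)^2)
    }
    for (m in jc_map) {
      A <- state_at(k, m[1]); B <- state_at(k, m[3])
      e <- joint_center_residual(pose(A$R, A$p), vals$offs[, m[2]],
                                 pose(B$R, B$p), vals$offs[, m[4]])
      err <- err + sum((Wj %*% e)^2)
    }
  }
  pri <- g$priors
  d2r <- pi / 180
  axseg <- list(list(1, 3, 4, "femur", "right"), list(2, 5, 6, "tibia", "right"),
                list(3, 8, 9, "femur", "left"), list(4, 10, 11, "tibia", "left"))
  for (a in axseg) {
    row <- pri$axis_segment[pri$axis_segment$segment == a[[4]] &
                              pri$axis_segment$side == a[[5]], ]
    e <- axis_segment_angle_residual(vals$axes[, a[[1]]], vals$offs[, a[[2]]],
                                     vals$offs[, a[[3]]],
                                     list(mu = row$mu_deg * d2r))
    err <- err + (e / (row$sigma_deg * d2r))^2
  }
  lens <- list(list("femur", 3, 4), list("femur", 8, 9), list("tibia", 5, 6),
               list("tibia", 10, 11), list("femoral_head_separation", 1, 2))
  for (l in lens) {
    row <- pri$lengths[pri$lengths$name == l[[1]], ]
    e <- segment_length_residual(vals$offs[, l[[2]]], vals$offs[, l[[3]]],
                                 list(mu = row$mu))
    err <- err + (e / row$sigma)^2
    x <- sqrt(sum((vals$offs[, l[[2]]] - vals$offs[, l[[3]]])^2))
    err <- err + length_window_penalty(
      x, list(lmin = row$lmin, lmax = row$lmax, a = pri$window_sharpness))^2
  }
  err <- err +
    (discrepancy_residual(vals$offs[, 3], vals$offs[, 4], vals$offs[, 8],
                          vals$offs[, 9]) /
       pri$discrepancy$sigma[pri$discrepancy$name == "femur"])^2 +
    (discrepancy_residual(vals$offs[, 5], vals$offs[, 6], vals$offs[, 10],
                          vals$offs[, 11]) /
       pri$discrepancy$sigma[pri$discrepancy$name == "tibia"])^2

  expect_equal(total_error(g, vals), err, tolerance = 1e-10)
})

test_that("pre-anchoring error is gauge invariant; anchoring breaks it", {
  g <- fx_graph_coarse()
  vals <- fx_vals_coarse()
  e0 <- total_error(g, vals)
  # global translation, constant velocity offset, heading rotation
  v1 <- gauge_transform(vals, g$t_kf, yaw = 0.7, dp = c(5, -3, 2),
                        dv = c(0.4, -0.2, 0.1))
  expect_lt(abs(total_error(g, v1) - e0) / e0, 1e-8)

  ga <- add_gauge_priors(g)
  # anchored values: shift truth so the first lumbar state is at the origin
  va <- gauge_transform(vals, g$t_kf,
                        yaw = -imumocap:::.euler_zyx(vals$R[, , 1])["yaw", 1] *
                          pi / 180)
  va <- gauge_transform(va, g$t_kf, dp = -va$p[, 1], dv = -va$v[, 1])
  ea <- total_error(ga, va)
  e_shift <- total_error(ga, gauge_transform(va, ga$t_kf, yaw = 0.3))
  expect_gt(e_shift - ea, 1)
})

test_that("initialization is deterministic with identity poses", {
  g <- fx_graph_tiny()
  i1 <- initialize_values(g)
  i2 <- initialize_values(g)
  expect_identical(i1, i2)
  expect_true(all(apply(i1$R, 3, function(R) identical(R, diag(3)))))
  expect_true(all(i1$p == 0) && all(i1$v == 0) && all(i1$b == 0))
  expect_true(is.finite(total_error(g, i1)))
  bad <- nominal_skeleton()
  bad$axes[, 2] <- c(1, 1, 0)
  expect_error(initialize_values(g, bad), "unit")
})

test_that("a static scene leaves axis and offset directions unidentified", {
  sk <- make_skeleton(seed = 5)
  sc <- script_motion_profile(30, seed = 5)
  sc$amplitude <- 0
  tr_static <- forward_kinematics(sk, sc, rate = 200, sway = FALSE)
  st_static <- synthesize_imu(tr_static, fx_noise(), noisy = FALSE)
  g_s <- add_gauge_priors(build_graph(st_static, fx_noise(),
                                      decimation = 500))
  v_s <- values_from_truth(g_s, tr_static)
  lin <- imumocap:::.lin_call(g_s, v_s, TRUE)
  # with no motion the hinge residual's axis Jacobian vanishes, so the
  # axis tangent columns are touched only by the 4 axis-segment priors
  axis_cols <- (g_s$dim - 43):(g_s$dim - 36)
  rows_touching_axes <- unique(lin$i[lin$j %in% axis_cols])
  expect_lte(length(rows_touching_axes), 4)
  J <- Matrix::sparseMatrix(i = lin$i, j = lin$j, x = lin$x,
                            dims = c(lin$nrow, g_s$dim))
  A <- as.matrix(Matrix::crossprod(J))
  ev_s <- eigen(A, symmetric = TRUE)
  n_null_static <- sum(ev_s$values < 1e-8 * max(ev_s$values))
  expect_gt(n_null_static, 3)
  # the null space is heavily enriched on the 44 static axis/offset dims
  # (uniform spread would put ~2.6% of the mass there)
  null_vec <- ev_s$vectors[, ncol(A) - seq_len(n_null_static) + 1, drop = FALSE]
  static_mass <- sum(null_vec[(g_s$dim - 43):g_s$dim, ]^2) / n_null_static
  expect_gt(static_mass, 0.2)

  # the moving dataset with the same layout is fully determined
  g_m <- add_gauge_priors(fx_graph_coarse())
  lin_m <- imumocap:::.lin_call(g_m, fx_vals_coarse(), TRUE)
  Jm <- Matrix::sparseMatrix(i = lin_m$i, j = lin_m$j, x = lin_m$x,
                             dims = c(lin_m$nrow, g_m$dim))
  Am <- as.matrix(Matrix::crossprod(Jm))
  ev_m <- eigen(Am, symmetric = TRUE, only.values = TRUE)
  n_null_moving <- sum(ev_m$values < 1e-8 * max(ev_m$values))
  expect_lt(n_null_moving, n_null_static)
})
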