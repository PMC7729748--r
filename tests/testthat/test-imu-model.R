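noise <- noise_spec()

test_that("integrate_step follows the first-order strapdown model", {
  # stationary upright IMU: gravity reaction cancels, position advances by v*dt
  s0 <- imu_state(v = c(0.5, 0, 0))
  s1 <- integrate_step(s0, c(0, 0, 0), c(0, 0, 9.81), noise)
  expect_equal(s1$v, s0$v, tolerance = 1e-12)
  expect_equal(s1$p, s0$p + s0$v * noise$dt, tolerance = 1e-12)
  expect_equal(s1$R, diag(3))

  # pure rotation: omega = (0,0,pi) for 0.5 s -> 90 degrees about z
  n2 <- noise_spec(dt = 0.5, g = c(0, 0, 0))
  s1 <- integrate_step(imu_state(), c(0, 0, pi), c(0, 0, 0), n2)
  expect_equal(s1$R, rot_exp(c(0, 0, pi / 2)), tolerance = 1e-12)

  # uniform acceleration: closed form within Euler discretization error
  n3 <- noise_spec(dt = 0.01, g = c(0, 0, 0))
  s <- imu_state()
  for (i in 1:100) s <- integrate_step(s, c(0, 0, 0), c(1, 0, 0), n3)
  expect_equal(s$v, c(1, 0, 0), tolerance = 1e-9)
  # with the half-step term the first-order scheme is exact for constant a
  expect_equal(s$p, c(0.5, 0, 0), tolerance = 1e-9)
})

test_that("preintegration compounds exactly like sequential integration", {
  gyro0 <- matrix(0, 5, 3)
  d0 <- preintegrate(gyro0, gyro0, noise)
  expect_equal(d0$dR, diag(3))
  expect_equal(d0$dv, rep(0, 3))
  expect_equal(d0$dp, rep(0, 3))

  set.seed(10)
  gyro <- matrix(rnorm(60, 0, 2), 20, 3)
  accel <- matrix(rnorm(60, 0, 5), 20, 3)
  b <- c(rnorm(3, 0, 0.01), rnorm(3, 0, 0.05))
  d <- preintegrate(gyro, accel, noise, lin_bias = b)
  s0 <- imu_state(R = rand_rotation(), p = rnorm(3), v = rnorm(3), b = b)
  s_seq <- s0
  for (k in 1:20) s_seq <- integrate_step(s_seq, gyro[k, ], accel[k, ], noise)
  s_pre <- preint_predict(d, s0, noise)
  expect_equal(s_pre$R, s_seq$R, tolerance = 1e-9)
  expect_equal(s_pre$v, s_seq$v, tolerance = 1e-9)
  expect_equal(s_pre$p, s_seq$p, tolerance = 1e-9)

  expect_error(preintegrate(gyro[0, , drop = FALSE], accel[0, , drop = FALSE],
                            noise), "at least one")
  expect_error(preintegrate(gyro, accel, noise,
                            t = c(seq(0, by = noise$dt, length.out = 19), 1)),
               "index 20")
})

test_that("preintegration composes over adjacent windows", {
  set.seed(11)
  gyro <- matrix(rnorm(120, 0, 1.5), 40, 3)
  accel <- matrix(rnorm(120, 0, 4), 40, 3)
  d_ij <- preintegrate(gyro[1:20, ], accel[1:20, ], noise)
  d_jk <- preintegrate(gyro[21:40, ], accel[21:40, ], noise)
  d_ik <- preintegrate(gyro, accel, noise)
  # compose: delta over (i,k) from the two halves
  expect_equal(d_ij$dR %*% d_jk$dR, d_ik$dR, tolerance = 1e-8)
  expect_equal(d_ij$dv + as.numeric(d_ij$dR %*% d_jk$dv), d_ik$dv,
               tolerance = 1e-8)
  expect_equal(d_ij$dp + d_ij$dv * d_jk$dT +
                 as.numeric(d_ij$dR %*% d_jk$dp), d_ik$dp, tolerance = 1e-8)
})

test_that("preintegrated deltas are independent of the gravity setting", {
  set.seed(12)
  gyro <- matrix(rnorm(30), 10, 3)
  accel <- matrix(rnorm(30), 10, 3)
  d1 <- preintegrate(gyro, accel, noise_spec(g = c(0, 0, -9.81)))
  d2 <- preintegrate(gyro, accel, noise_spec(g = c(0, 0, 0)))
  expect_identical(d1$dR, d2$dR)
  expect_identical(d1$dp, d2$dp)
  # but gravity enters the residual: same states, different g
  si <- imu_state()
  sj <- preint_predict(d1, si, noise_spec(g = c(0, 0, -9.81)))
  expect_equal(preint_residual(d1, si, sj, noise_spec(g = c(0, 0, -9.81))),
               rep(0, 9), tolerance = 1e-9)
  expect_gt(max(abs(preint_residual(d1, si, sj, noise_spec(g = c(0, 0, 0))))),
            0.01)
})

test_that("propagated preintegration covariance matches Monte-Carlo", {
  set.seed(13)
  n <- 20
  w_true <- matrix(rnorm(3 * n, 0, 1), 3)
  a_true <- matrix(rnorm(3 * n, 0, 2), 3)
  d0 <- preintegrate(t(w_true), t(a_true), noise)
  K <- 1200
  errs <- matrix(0, K, 9)
  sw <- noise$sigma_w / sqrt(noise$dt)
  sa <- noise$sigma_a / sqrt(noise$dt)
  for (k in 1:K) {
    dk <- preintegrate(t(w_true + matrix(rnorm(3 * n, 0, sw), 3)),
                       t(a_true + matrix(rnorm(3 * n, 0, sa), 3)), noise)
    errs[k, ] <- c(rot_log(t(d0$dR) %*% dk$dR), dk$dv - d0$dv, dk$dp - d0$dp)
  }
  ratio <- diag(stats::cov(errs)) / diag(d0$cov)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("preintegration residual is zero on consistent states and local", {
  set.seed(14)
  gyro <- matrix(rnorm(60, 0, 1), 20, 3)
  accel <- matrix(rnorm(60, 0, 3), 20, 3)
  d <- preintegrate(gyro, accel, noise)
  si <- imu_state(R = rand_rotation(), p = rnorm(3), v = rnorm(3))
  sj <- preint_predict(d, si, noise)
  expect_equal(preint_residual(d, si, sj, noise), rep(0, 9), tolerance = 1e-9)

  # perturbing position j shows up in the (unwhitened) position block
  sj2 <- sj; sj2$p <- sj$p + c(0, 0, 0.1)
  r <- preint_residual(d, si, sj2, noise)
  expect_equal(sqrt(sum(r[7:9]^2)), 0.1, tolerance = 1e-12)
  expect_equal(r[1:6], rep(0, 6), tolerance = 1e-9)

  # first-order bias correction agrees with re-preintegration to O(|db|^2)
  db <- c(0.001, -0.002, 0.0015, 0.01, -0.02, 0.015)
  si_b <- si; si_b$b <- db
  sj_b <- sj; sj_b$b <- db
  r_corr <- preint_residual(d, si_b, sj_b, noise)
  d_re <- preintegrate(gyro, accel, noise, lin_bias = db)
  r_re <- preint_residual(d_re, si_b, sj_b, noise)
  expect_lt(max(abs(r_corr - r_re)), 50 * sum(db^2))
})

test_that("bias random-walk residual whitens as 1/sqrt(dT)", {
  expect_equal(bias_residual(rep(0.1, 6), rep(0.1, 6)), rep(0, 6))
  r <- bias_residual(rep(0, 6), c(1e-3, 0, 0, 0, 0, 0))
  expect_equal(r[1:3], c(1e-3, 0, 0))
  r1 <- bias_residual(rep(0, 6), rep(1e-3, 6), dT = 1, noise, whiten = TRUE)
  r4 <- bias_residual(rep(0, 6), rep(1e-3, 6), dT = 4, noise, whiten = TRUE)
  expect_equal(r1 / r4, rep(2, 6), tolerance = 1e-12)
})

test_that("angular-velocity residual ties estimate, bias and measurement", {
  expect_equal(angvel_residual(c(1, 2, 3), rep(0, 3), c(1, 2, 3)), rep(0, 3))
  expect_equal(angvel_residual(c(1, 0, 0), c(0.01, 0, 0), c(1.01, 0, 0)),
               rep(0, 3))
  expect_equal(angvel_residual(c(1, 2, 3), rep(0, 3), c(1, 2, 2.9)),
               c(0, 0, 0.1))
})

test_that("whitened preintegration residuals have unit variance under noise", {
  set.seed(15)
  n <- 20
  w_true <- matrix(rnorm(3 * n, 0, 1), 3)
  a_true <- matrix(rnorm(3 * n, 0, 2), 3)
  sw <- noise$sigma_w / sqrt(noise$dt)
  sa <- noise$sigma_a / sqrt(noise$dt)
  si <- imu_state(R = rand_rotation(), v = rnorm(3))
  d0 <- preintegrate(t(w_true), t(a_true), noise)
  sj <- preint_predict(d0, si, noise)
  K <- 1000
  rw <- matrix(0, K, 9)
  for (k in 1:K) {
    dk <- preintegrate(t(w_true + matrix(rnorm(3 * n, 0, sw), 3)),
                       t(a_true + matrix(rnorm(3 * n, 0, sa), 3)), noise)
    rw[k, ] <- preint_residual(dk, si, sj, noise, whiten = TRUE)
  }
  v <- apply(rw, 2, stats::var)
  expect_true(all(v > 0.8 & v < 1.2))
})
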