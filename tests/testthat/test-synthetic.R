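test_that("skeleton sampling is deterministic and respects the priors", {
  s1 <- make_skeleton(seed = 7)
  s2 <- make_skeleton(seed = 7)
  expect_identical(s1, s2)
  pri <- default_anthro_priors()
  fem <- pri$lengths[pri$lengths$name == "femur", ]
  tib <- pri$lengths[pri$lengths$name == "tibia", ]
  for (sd in 1:20) {
    sk <- make_skeleton(seed = sd)
    expect_true(all(sk$femur >= fem$lmin & sk$femur <= fem$lmax))
    expect_true(all(sk$tibia >= tib$lmin & sk$tibia <= tib$lmax))
    th <- sk$axis_angles_deg
    expect_lt(abs(th$fr - 84), 3 * 2.4 + 1e-9)
    expect_lt(abs(th$tr - 92), 3 * 1.2 + 1e-9)
    expect_lt(abs(th$fl - 96), 3 * 2.4 + 1e-9)
    expect_lt(abs(th$tl - 88), 3 * 1.2 + 1e-9)
  }
})

test_that("motion profile excites every lower-body DOF in order", {
  expect_error(script_motion_profile(20), "at least 30")
  sc <- script_motion_profile(60, seed = 1)
  expect_identical(sc, script_motion_profile(60, seed = 1))
  knee <- sc[sc$joint == "knee", ]
  expect_true(all(abs(knee$amplitude) >= 90))
  expect_true(all(knee$reps >= 3))
  # every joint/side/dof combination present
  for (sd in c("right", "left")) {
    expect_true(any(sc$joint == "ankle" & sc$side == sd & sc$dof == "fe"))
    expect_true(any(sc$joint == "ankle" & sc$side == sd & sc$dof == "circle"))
    expect_true(any(sc$joint == "knee" & sc$side == sd))
    for (d in c("fe", "ab", "rot"))
      expect_true(any(sc$joint == "hip" & sc$side == sd & sc$dof == d))
  }
  expect_true(all(c("bend", "twist", "side") %in%
                    sc$dof[sc$joint == "pelvis"]))
  # windows are ordered and non-overlapping
  expect_true(all(diff(sc$t0) > 0))
  expect_true(all(sc$t1 > sc$t0))
})

test_that("zero-amplitude script yields constant poses and zero velocities", {
  sk <- make_skeleton(seed = 5)
  sc <- script_motion_profile(30, seed = 5)
  sc$amplitude <- 0
  tr <- forward_kinematics(sk, sc, rate = 50, sway = FALSE)
  for (s in c(1, 4, 6)) {
    imu <- tr$imus[[s]]
    expect_lt(max(abs(imu$v)), 1e-12)
    expect_lt(max(abs(imu$w)), 1e-12)
    expect_lt(max(abs(imu$R[, , 1] - imu$R[, , tr$n])), 1e-12)
    expect_lt(max(abs(imu$p[, 1] - imu$p[, tr$n])), 1e-12)
  }
})

test_that("forward kinematics is exactly hinge- and joint-coherent", {
  tr <- fx_truth()
  # hinge: residual of the true axis below 1e-10 at every sample
  m_r <- imumocap:::.rotarr_vec(
    imumocap:::.rotarr_tmul(tr$imus[[2]]$R, tr$imus[[3]]$R),
    tr$imus[[3]]$w) - tr$imus[[2]]$w
  e <- m_r - outer(tr$axes_true[, 1], colSums(m_r * tr$axes_true[, 1]))
  expect_lt(max(abs(e)), 1e-10)
  # joint-center coherence at every sample (left knee)
  pA <- imumocap:::.rotarr_vec(tr$imus[[5]]$R, tr$offs_true[, 9]) +
    tr$imus[[5]]$p
  pB <- imumocap:::.rotarr_vec(tr$imus[[6]]$R, tr$offs_true[, 10]) +
    tr$imus[[6]]$p
  expect_lt(max(abs(pA - pB)), 1e-10)
  # numerical differentiation of positions matches stored velocities O(dt^2)
  dt <- 1 / tr$rate
  for (s in c(2, 7)) {
    imu <- tr$imus[[s]]
    vfd <- (imu$p[, 3:tr$n] - imu$p[, 1:(tr$n - 2)]) / (2 * dt)
    expect_lt(max(abs(vfd - imu$v[, 2:(tr$n - 1)])), 5e-3)
  }
  # and of velocities against accelerations; the joint-angle signals are C^2
  # (not C^3), so the central difference is contaminated at isolated
  # smoothstep-junction samples -- compare away from the extreme quantile
  imu <- tr$imus[[3]]
  afd <- (imu$v[, 3:tr$n] - imu$v[, 1:(tr$n - 2)]) / (2 * dt)
  err <- abs(afd - imu$a[, 2:(tr$n - 1)])
  expect_lt(stats::quantile(err, 0.95), 0.05)
  expect_lt(max(err), 3)
})

test_that("synthesized measurements follow the sensor model", {
  sk <- make_skeleton(seed = 5)
  sc <- script_motion_profile(30, seed = 5)
  sc$amplitude <- 0
  tr <- forward_kinematics(sk, sc, rate = 200, sway = FALSE)
  # static noise-free IMU: zero gyro, accelerometer reads the gravity reaction
  st <- synthesize_imu(tr, noise_spec(), noisy = FALSE, mode = "sampled")
  for (s in 1:7) {
    expect_lt(max(abs(st[[s]]$gyro)), 1e-12)
    f_body <- st[[s]]$accel[1, ]
    expect_equal(sqrt(sum(f_body^2)), 9.81, tolerance = 1e-9)
    # specific force rotated to navigation = -g
    expect_equal(as.numeric(tr$imus[[s]]$R[, , 1] %*% f_body), c(0, 0, 9.81),
                 tolerance = 1e-9)
  }
  # discrete-consistent mode agrees in the static case
  std <- synthesize_imu(tr, noise_spec(), noisy = FALSE, mode = "discrete")
  expect_equal(std[[2]]$accel, st[[2]]$accel, tolerance = 1e-9)

  # gyro white-noise variance matches sigma_w^2 / dt within 5%
  noise <- noise_spec()
  stn <- synthesize_imu(tr, noise, seed = 9, noisy = TRUE)
  b <- attr(stn, "bias_true")
  resid <- unlist(lapply(1:7, function(s) stn[[s]]$gyro - t(b[[s]][1:3, ])))
  expect_equal(stats::var(resid), noise$sigma_w^2 / noise$dt,
               tolerance = 0.05)

  expect_identical(stn, synthesize_imu(tr, noise, seed = 9, noisy = TRUE))
})

test_that("soft-tissue perturbation is zero-mean, bounded and optional", {
  tr <- fx_truth()
  expect_identical(perturb_soft_tissue(tr, 0, 0), tr)
  # translation-only: per-sample joint-center residual norms within 2x the
  # amplitude, zero mean over the trajectory
  trp <- perturb_soft_tissue(tr, amplitude_mm = 5, amplitude_deg = 0,
                             frequency = 1, seed = 2)
  pA <- imumocap:::.rotarr_vec(trp$imus[[5]]$R, trp$offs_true[, 9]) +
    trp$imus[[5]]$p
  pB <- imumocap:::.rotarr_vec(trp$imus[[6]]$R, trp$offs_true[, 10]) +
    trp$imus[[6]]$p
  nr <- sqrt(colSums((pA - pB)^2))
  expect_lt(max(nr), 2 * 5e-3 + 1e-9)
  expect_gt(max(nr), 1e-3)           # it does perturb
  expect_lt(max(abs(rowMeans(pA - pB))), 7e-4)  # ~zero-mean over trajectory
  # with a rotational component the relative angular-velocity cloud spreads
  # off the axis (the characteristic double cone)
  trq <- perturb_soft_tissue(tr, amplitude_mm = 5, amplitude_deg = 1,
                             frequency = 1, seed = 2)
  m_r <- imumocap:::.rotarr_vec(
    imumocap:::.rotarr_tmul(trq$imus[[2]]$R, trq$imus[[3]]$R),
    trq$imus[[3]]$w) - trq$imus[[2]]$w
  e <- m_r - outer(tr$axes_true[, 1], colSums(m_r * tr$axes_true[, 1]))
  expect_gt(stats::sd(sqrt(colSums(e^2))), 1e-3)
})

test_that("one-call dataset simulation is reproducible", {
  n <- noise_spec()
  a <- simulate_dataset(duration = 30, seed = 5, noise = n, rate = 50,
                        noisy = TRUE)
  b <- simulate_dataset(duration = 30, seed = 5, noise = n, rate = 50,
                        noisy = TRUE)
  expect_identical(a$streams, b$streams)
  expect_identical(a$truth$axes_true, b$truth$axes_true)
})
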