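# Shared fixtures, memoized so the expensive kinematic-chain simulation and
# graph assembly run once per test session.

fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = fx_env, inherits = FALSE))
    assign(name, builder(), envir = fx_env)
  get(name, envir = fx_env)
}

# noise spec consistent with the simulated sensors: the keyframe gyro
# residual sees the discrete-time sample noise sigma_w / sqrt(dt)
fx_noise <- function() noise_spec(sigma_g = 0.005 / sqrt(1 / 200))

fx_truth <- function() fx("truth", function() {
  forward_kinematics(make_skeleton(seed = 3),
                     script_motion_profile(30, seed = 4), 200)
})

fx_streams_clean <- function() fx("streams_clean", function() {
  synthesize_imu(fx_truth(), fx_noise(), noisy = FALSE)
})

# truncate aligned streams to the first n samples
truncate_streams <- function(streams, n) {
  out <- lapply(streams, function(s)
    list(t = s$t[1:n], gyro = s$gyro[1:n, , drop = FALSE],
         accel = s$accel[1:n, , drop = FALSE]))
  class(out) <- "imu_streams"
  out
}

# M = 3 graph on 41 samples (decimation 20)
fx_graph_tiny <- function() fx("graph_tiny", function() {
  build_graph(truncate_streams(fx_streams_clean(), 41), fx_noise())
})

# M = 13 graph spanning the whole 30 s profile (decimation 500);
# small enough for dense spectral checks, with real excitation
fx_graph_coarse <- function() fx("graph_coarse", function() {
  build_graph(fx_streams_clean(), fx_noise(), decimation = 500)
})

fx_vals_coarse <- function() fx("vals_coarse", function() {
  values_from_truth(fx_graph_coarse(), fx_truth())
})

# moderately sized graph for optimizer recovery tests (decimation 40, M = 151)
fx_graph_small <- function() fx("graph_small", function() {
  build_graph(fx_streams_clean(), fx_noise(), decimation = 40)
})

# a solution object holding ground-truth values (for anatomy tests)
fx_solution_truth <- function() fx("sol_truth", function() {
  g <- fx_graph_small()
  structure(list(values = values_from_truth(g, fx_truth()), M = g$M,
                 t = g$t_kf, decimation = g$decimation),
            class = "imu_solution")
})

# ground-truth solution for a knee-flexion-rich trajectory (median flexion
# around -50 degrees), needed to exercise the sign-disambiguation logic whose
# median test presumes the knee spends substantial time flexed
fx_solution_knee <- function() fx("sol_knee", function() {
  sk <- make_skeleton(seed = 6)
  sc <- data.frame(joint = c("knee", "knee"), side = c("right", "left"),
                   dof = "flex", type = "pulse", amplitude = -100,
                   reps = 9, t0 = 0, t1 = 30, stringsAsFactors = FALSE)
  attr(sc, "duration") <- 30
  class(sc) <- c("motion_script", "data.frame")
  tr <- forward_kinematics(sk, sc, rate = 50)
  n50 <- noise_spec(dt = 1 / 50)
  st <- synthesize_imu(tr, n50, noisy = FALSE)
  g <- build_graph(st, n50, decimation = 10)
  structure(list(values = values_from_truth(g, tr), M = g$M, t = g$t_kf,
                 decimation = g$decimation), class = "imu_solution")
})

rand_rotation <- function() rot_exp(rnorm(3))

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
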