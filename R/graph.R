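# Factor-graph assembly for the full seven-IMU lower-body problem.
#
# Variable tangent layout (per keyframe k = 1..M, IMU s = 1..7):
#   rotation (3), position (3), velocity (3), angular velocity (3), bias (6)
# i.e. 18 dims per state, 126 per keyframe, followed by 44 static dims
# (4 knee axes x 2 sphere-tangent dims, 12 joint-center offsets x 3).

#' Assemble the lower-body factor graph
#'
#' Preintegrates every inter-keyframe measurement window for all seven IMUs
#' and records the full factor bookkeeping: per keyframe interval a
#' preintegration and a bias random-walk factor per IMU; per keyframe an
#' angular-velocity factor per IMU, four hinge factors (proximal and distal
#' axis of each knee) and six joint-center factors (hips, knees, ankles);
#' plus the static anthropometric factors (four axis-segment angle priors,
#' five length priors, five window penalties, two cross-leg discrepancies).
#' Axis-segment and anthropometric factors involve only static variables and
#' are included once; replicating them per keyframe would merely rescale
#' their weight with trajectory length (equivalently, divide their sigma by
#' `sqrt(M)`).
#'
#' @param streams list of 7 IMU streams (elements `t`, `gyro` N x 3,
#'   `accel` N x 3), time-aligned and equal length; IMU order lumbar, right
#'   thigh, right shank, right foot, left thigh, left shank, left foot.
#' @param noise a [noise_spec()].
#' @param priors anthropometric priors, see [default_anthro_priors()].
#' @param decimation samples per keyframe interval.
#' @return object of class `"imu_graph"` with factor `counts`, total tangent
#'   `dim` (`126 M + 44`), keyframe times `t_kf`, and the preintegrated data.
#' @export
build_graph <- function(streams, noise = noise_spec(),
                        priors = default_anthro_priors(),
                        decimation = noise$decimation) {
  if (length(streams) != 7)
    stop("build_graph requires exactly 7 IMU streams, got ", length(streams))
  t0 <- streams[[1]]$t
  for (s in 2:7) {
    if (length(streams[[s]]$t) != length(t0) ||
        max(abs(streams[[s]]$t - t0)) > 1e-9)
      stop("misaligned timestamps between IMU 1 and IMU ", s)
  }
  N <- length(t0)
  decimation <- as.integer(decimation)
  if (N < 2L * decimation)
    stop("stream too short: need at least 2*decimation = ", 2 * decimation,
         " samples, got ", N)
  steps <- diff(t0)
  dt <- stats::median(steps)
  bad <- which(abs(steps - dt) > 1e-6)
  if (length(bad))
    stop("non-uniform sample times at index ", bad[1] + 1)
  noise$dt <- dt

  M <- as.integer((N - 1) %/% decimation + 1L)
  ki <- 1L + (0:(M - 1L)) * decimation
  n_int <- 7L * (M - 1L)

  pre_dR <- array(0, c(3, 3, n_int))
  pre_dv <- matrix(0, 3, n_int)
  pre_dp <- matrix(0, 3, n_int)
  pre_Jb <- array(0, c(9, 6, n_int))
  pre_Linv <- array(0, c(9, 9, n_int))
  pre_bbar <- matrix(0, 6, n_int)
  pre_dT <- numeric(n_int)
  kf_gyro <- matrix(0, 3, 7L * M)

  for (s in 1:7) {
    g3 <- t(streams[[s]]$gyro)
    a3 <- t(streams[[s]]$accel)
    kf_gyro[, seq(s, by = 7, length.out = M)] <- g3[, ki]
    for (k in seq_len(M - 1L)) {
      cols <- ki[k]:(ki[k + 1L] - 1L)
      pd <- preintegrate_cpp(g3[, cols, drop = FALSE],
                             a3[, cols, drop = FALSE], dt,
                             rep(0, 3), rep(0, 3),
                             noise$sigma_w, noise$sigma_a)
      idx <- (k - 1L) * 7L + s
      pre_dR[, , idx] <- pd$dR
      pre_dv[, idx] <- pd$dv
      pre_dp[, idx] <- pd$dp
      pre_Jb[, , idx] <- pd$Jb
      pre_Linv[, , idx] <- pd$Linv
      pre_dT[idx] <- pd$dT
    }
  }

  axs <- priors$axis_segment
  asrow <- function(seg, sd, axis, op, od) {
    r <- axs[axs$segment == seg & axs$side == sd, ]
    c(axis, op, od, r$mu_deg * pi / 180, r$sigma_deg * pi / 180)
  }
  axseg_rows <- rbind(asrow("femur", "right", 1, 3, 4),
                      asrow("tibia", "right", 2, 5, 6),
                      asrow("femur", "left", 3, 8, 9),
                      asrow("tibia", "left", 4, 10, 11))
  len <- priors$lengths
  lrow <- function(nm, o1, o2) {
    r <- len[len$name == nm, ]
    c(o1, o2, r$mu, r$sigma)
  }
  len_rows <- rbind(lrow("femur", 3, 4), lrow("femur", 8, 9),
                    lrow("tibia", 5, 6), lrow("tibia", 10, 11),
                    lrow("femoral_head_separation", 1, 2))
  wrow <- function(nm, o1, o2) {
    r <- len[len$name == nm, ]
    c(o1, o2, r$lmin, r$lmax, priors$window_sharpness)
  }
  win_rows <- rbind(wrow("femur", 3, 4), wrow("femur", 8, 9),
                    wrow("tibia", 5, 6), wrow("tibia", 10, 11),
                    wrow("femoral_head_separation", 1, 2))
  disc <- priors$discrepancy
  disc_rows <- rbind(c(3, 4, 8, 9, disc$sigma[disc$name == "femur"]),
                     c(5, 6, 10, 11, disc$sigma[disc$name == "tibia"]))

  counts <- list(preintegration = 7L * (M - 1L), bias_walk = 7L * (M - 1L),
                 angular_velocity = 7L * M, hinge = 4L * M,
                 joint_center = 6L * M, axis_segment = 4L, length = 5L,
                 window = 5L, discrepancy = 2L)

  structure(list(
    M = M, dt = dt, decimation = decimation, t_kf = t0[ki],
    noise = noise, priors = priors,
    pre = list(dR = pre_dR, dv = pre_dv, dp = pre_dp, Jb = pre_Jb,
               Linv = pre_Linv, bbar = pre_bbar, dT = pre_dT),
    kf_gyro = kf_gyro,
    tables = list(
      jc_pairs = rbind(c(1L, 1L, 2L, 3L), c(2L, 4L, 3L, 5L),
                       c(3L, 6L, 4L, 7L), c(1L, 2L, 5L, 8L),
                       c(5L, 9L, 6L, 10L), c(6L, 11L, 7L, 12L)),
      hinge_rows = rbind(c(1L, 2L, 3L), c(2L, 3L, 2L),
                         c(3L, 5L, 6L), c(4L, 6L, 5L)),
      axseg_rows = axseg_rows, len_rows = len_rows,
      win_rows = win_rows, disc_rows = disc_rows),
    Linv_g = .whitener(noise$Sigma_g),
    Linv_K = .whitener(noise$Sigma_K),
    Linv_j = .whitener(noise$Sigma_j),
    bw_sigma = c(rep(noise$sigma_bw_g, 3), rep(noise$sigma_bw_a, 3)),
    gauge = FALSE,
    gauge_sigma = c(pos = 1e-3, vel = 1e-3, yaw = 1e-3, bg0 = 0.02,
                    ba0 = 0.1, vel_weak = 2),
    counts = counts, dim = 126L * M + 44L
  ), class = "imu_graph")
}

#' Anchor the gauge freedoms
#'
#' Without an absolute position or heading reference the solution is only
#' determined up to a global translation, constant velocity offset, and
#' rotation about gravity. This adds priors of zero position, zero velocity
#' and zero heading (a 1-DOF residual on the yaw of a Z-Y-X Euler
#' decomposition) on the first lumbar keyframe state, plus weak priors on
#' the initial biases of all IMUs.
#'
#' First-keyframe anchors alone leave one further exactly flat mode: a
#' global tilt about a horizontal axis combined with a compensating linear
#' velocity drift `(g - Gg) t` and quadratic position drift, under which
#' every measurement factor is invariant. A weak zero-mean bounded-speed
#' prior (`sigma_vel_weak`, default 2 m/s -- generous for the sacrum during
#' this kind of protocol) on the lumbar velocity at every keyframe pins this
#' mode while leaving physically plausible velocities essentially
#' unpenalized.
#'
#' @param graph an [build_graph()] result.
#' @param sigma_pos,sigma_vel,sigma_yaw anchor stds (m, m/s, rad).
#' @param sigma_bg0,sigma_ba0 initial-bias prior stds (rad/s, m/s^2).
#' @param sigma_vel_weak bounded-speed prior std (m/s).
#' @return the graph with gauge anchoring enabled.
#' @export
add_gauge_priors <- function(graph, sigma_pos = 1e-3, sigma_vel = 1e-3,
                             sigma_yaw = 1e-3, sigma_bg0 = 0.02,
                             sigma_ba0 = 0.1, sigma_vel_weak = 2) {
  graph$gauge <- TRUE
  graph$gauge_sigma <- c(pos = sigma_pos, vel = sigma_vel, yaw = sigma_yaw,
                         bg0 = sigma_bg0, ba0 = sigma_ba0,
                         vel_weak = sigma_vel_weak)
  # position, velocity, yaw, 7 bias priors, M bounded-speed priors
  graph$counts$gauge <- 10L + graph$M
  graph
}

#' Nominal skeleton alignment for initialization
#'
#' Knee axes along the IMU x-axis; thigh/shank offsets 0.2 m along the IMU
#' z-axis toward the proximal/distal joint; lumbar-to-hip offsets
#' (+-0.09, 0, -0.1) m; foot-to-ankle offsets (0, 0, 0.1) m.
#'
#' @return list with `axes` (3 x 4) and `offs` (3 x 12).
#' @export
nominal_skeleton <- function() {
  axes <- matrix(rep(c(1, 0, 0), 4), 3, 4,
                 dimnames = list(NULL, c("r2", "r3", "r5", "r6")))
  offs <- cbind(c(0.09, 0, -0.1), c(-0.09, 0, -0.1),
                c(0, 0, 0.2), c(0, 0, -0.2),
                c(0, 0, 0.2), c(0, 0, -0.2),
                c(0, 0, 0.1),
                c(0, 0, 0.2), c(0, 0, -0.2),
                c(0, 0, 0.2), c(0, 0, -0.2),
                c(0, 0, 0.1))
  colnames(offs) <- .offset_names()
  list(axes = axes, offs = offs)
}

#' Initial value assignment
#'
#' Positions, velocities, angular velocities and biases start at zero and
#' orientations at identity; knee axes and joint-center offsets come from
#' the assumed nominal alignment. Deterministic.
#'
#' @param graph an [build_graph()] result.
#' @param nominal a [nominal_skeleton()]-shaped list.
#' @return a value assignment (list with `R`, `p`, `v`, `w`, `b`, `axes`,
#'   `offs`, `M`).
#' @export
initialize_values <- function(graph, nominal = nominal_skeleton()) {
  M <- graph$M
  n <- 7L * M
  for (a in 1:4) .check_unit(nominal$axes[, a])
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- R[2, 2, ] <- R[3, 3, ] <- 1
  list(R = R, p = matrix(0, 3, n), v = matrix(0, 3, n), w = matrix(0, 3, n),
       b = matrix(0, 6, n), axes = nominal$axes, offs = nominal$offs, M = M)
}

#' Value assignment from synthetic ground truth
#'
#' Samples the true trajectory at the graph's keyframes. Used in validation:
#' on noise-free data the total error at the truth is (numerically) the
#' global minimum.
#'
#' @param graph an [build_graph()] result.
#' @param truth a [forward_kinematics()] result at the same rate.
#' @param biases optional list of true 6 x N bias series (from the
#'   `bias_true` attribute of [synthesize_imu()]).
#' @return a value assignment.
#' @export
values_from_truth <- function(graph, truth, biases = NULL) {
  M <- graph$M
  ki <- 1L + (0:(M - 1L)) * graph$decimation
  stopifnot(max(ki) <= truth$n)
  n <- 7L * M
  R <- array(0, c(3, 3, n))
  p <- v <- w <- matrix(0, 3, n)
  b <- matrix(0, 6, n)
  for (s in 1:7) {
    idx <- seq(s, by = 7, length.out = M)
    R[, , idx] <- truth$imus[[s]]$R[, , ki]
    p[, idx] <- truth$imus[[s]]$p[, ki]
    v[, idx] <- truth$imus[[s]]$v[, ki]
    w[, idx] <- truth$imus[[s]]$w[, ki]
    if (!is.null(biases)) b[, idx] <- biases[[s]][, ki]
  }
  list(R = R, p = p, v = v, w = w, b = b,
       axes = truth$axes_true, offs = truth$offs_true, M = M)
}

.lin_call <- function(graph, values, want_jac) {
  linearize_graph_cpp(
    graph$M, values$R, values$p, values$v, values$w, values$b,
    values$axes, values$offs,
    graph$pre$dR, graph$pre$dv, graph$pre$dp, graph$pre$Jb, graph$pre$Linv,
    graph$pre$bbar, graph$pre$dT, graph$kf_gyro, graph$noise$g,
    graph$Linv_g, graph$Linv_K, graph$Linv_j, graph$bw_sigma,
    graph$tables$jc_pairs, graph$tables$hinge_rows, graph$tables$axseg_rows,
    graph$tables$len_rows, graph$tables$win_rows, graph$tables$disc_rows,
    graph$gauge, graph$gauge_sigma, want_jac)
}

#' Total whitened squared error
#'
#' Sum over all factors of the squared Mahalanobis norm of the residual.
#'
#' @param graph an [build_graph()] result.
#' @param values a complete value assignment.
#' @return nonnegative scalar.
#' @export
total_error <- function(graph, values) {
  .lin_call(graph, values, FALSE)$err
}

#' Per-factor-category error breakdown
#' @inheritParams total_error
#' @return named numeric vector of whitened squared error by category.
#' @export
error_breakdown <- function(graph, values) {
  .lin_call(graph, values, FALSE)$group_err
}

.retract_values <- function(values, delta) {
  out <- retract_values_cpp(values$R, values$p, values$v, values$w, values$b,
                            values$axes, values$offs, delta, values$M)
  out$M <- values$M
  dimnames(out$axes) <- dimnames(values$axes)
  dimnames(out$offs) <- dimnames(values$offs)
  out
}

# Apply a gauge transformation (global heading rotation G about z, position
# offset, constant velocity offset) to a value assignment; used to verify
# gauge invariance. Positions shift by `dp + dv * (t - t[1])`.
gauge_transform <- function(values, t_kf, yaw = 0, dp = c(0, 0, 0),
                            dv = c(0, 0, 0)) {
  G <- rot_exp(c(0, 0, yaw))
  n <- 7L * values$M
  tt <- rep(t_kf - t_kf[1], each = 7)
  for (i in seq_len(n)) {
    values$R[, , i] <- G %*% values$R[, , i]
    values$p[, i] <- as.numeric(G %*% values$p[, i]) + dp + dv * tt[i]
    values$v[, i] <- as.numeric(G %*% values$v[, i]) + dv
  }
  values
}
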