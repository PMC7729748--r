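# Ground-truth generator: a lower-body kinematic chain (pelvis root, 3-DOF
# ball hips and ankles, 1-DOF hinge knees) driven by C^2 joint-angle signals,
# with analytic angular velocity and acceleration propagated through the
# chain so that synthesized IMU measurements have exact ground truth.

# ---- deterministic seeding -------------------------------------------------

.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  fn()
}

# ---- C^2 scalar signals ----------------------------------------------------

# Quintic smoothstep and derivatives; zero value/slope/curvature at both ends.
.ss <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}
.ssp <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  30 * u^2 * (1 - u)^2
}
.sspp <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  60 * u * (2 * u^2 - 3 * u + 1)
}

# Single 0 -> 1 -> 0 bump on u in [0,1]; C^2 everywhere.
.bump <- function(u) {
  lo <- u < 0.5
  w <- ifelse(lo, .ss(2 * u), .ss(2 - 2 * u))
  wp <- ifelse(lo, 2 * .ssp(2 * u), -2 * .ssp(2 - 2 * u))
  wpp <- ifelse(lo, 4 * .sspp(2 * u), 4 * .sspp(2 - 2 * u))
  list(w = w, wp = wp, wpp = wpp)
}

# Train of `reps` bumps of amplitude A (rad) over [t0, t1].
.pulse_train <- function(t, t0, t1, reps, A) {
  q <- qd <- qdd <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  if (any(inside)) {
    dur <- (t1 - t0) / reps
    u <- ((t[inside] - t0) / dur) %% 1
    u[t[inside] == t1] <- 1
    b <- .bump(u)
    q[inside] <- A * b$w
    qd[inside] <- A * b$wp / dur
    qdd[inside] <- A * b$wpp / dur^2
  }
  list(q = q, qd = qd, qdd = qdd)
}

# Enveloped oscillation: A * bump(u) * sin(2 pi cycles u + phase) on [t0,t1].
.osc_train <- function(t, t0, t1, cycles, A, phase = 0) {
  q <- qd <- qdd <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  if (any(inside)) {
    Tw <- t1 - t0
    u <- (t[inside] - t0) / Tw
    b <- .bump(u)
    om <- 2 * pi * cycles
    s <- sin(om * u + phase); cs <- cos(om * u + phase)
    q[inside] <- A * b$w * s
    qd[inside] <- A * (b$wp * s + b$w * om * cs) / Tw
    qdd[inside] <- A * (b$wpp * s + 2 * b$wp * om * cs - b$w * om^2 * s) / Tw^2
  }
  list(q = q, qd = qd, qdd = qdd)
}

.zero_sig <- function(n) list(q = numeric(n), qd = numeric(n), qdd = numeric(n))
.add_sig <- function(a, b) list(q = a$q + b$q, qd = a$qd + b$qd, qdd = a$qdd + b$qdd)

# ---- vectorized rotation arrays (3 x 3 x N) --------------------------------

.rots_axis <- function(axis, q) {
  n <- length(q)
  K <- skew3_r(axis)
  K2 <- K %*% K
  R <- array(0, c(3, 3, n))
  s <- sin(q); cc <- 1 - cos(q)
  for (i in 1:3) for (j in 1:3)
    R[i, j, ] <- (i == j) + s * K[i, j] + cc * K2[i, j]
  R
}

skew3_r <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

.rotarr_mul <- function(A, B) {  # A_k %*% B_k
  C <- array(0, dim(A))
  for (i in 1:3) for (j in 1:3)
    C[i, j, ] <- A[i, 1, ] * B[1, j, ] + A[i, 2, ] * B[2, j, ] + A[i, 3, ] * B[3, j, ]
  C
}

.rotarr_mulc <- function(A, B0) {  # A_k %*% B0
  C <- array(0, dim(A))
  for (i in 1:3) for (j in 1:3)
    C[i, j, ] <- A[i, 1, ] * B0[1, j] + A[i, 2, ] * B0[2, j] + A[i, 3, ] * B0[3, j]
  C
}

.rotarr_tmul <- function(A, B) {  # t(A_k) %*% B_k
  C <- array(0, dim(A))
  for (i in 1:3) for (j in 1:3)
    C[i, j, ] <- A[1, i, ] * B[1, j, ] + A[2, i, ] * B[2, j, ] + A[3, i, ] * B[3, j, ]
  C
}

.rotarr_vec <- function(A, x) {  # A_k %*% x_k ; x is 3 x N or length-3
  if (is.null(dim(x))) x <- matrix(x, 3, dim(A)[3])
  y <- matrix(0, 3, dim(A)[3])
  for (i in 1:3)
    y[i, ] <- A[i, 1, ] * x[1, ] + A[i, 2, ] * x[2, ] + A[i, 3, ] * x[3, ]
  y
}

.rotarr_tvec <- function(A, x) {  # t(A_k) %*% x_k
  if (is.null(dim(x))) x <- matrix(x, 3, dim(A)[3])
  y <- matrix(0, 3, dim(A)[3])
  for (i in 1:3)
    y[i, ] <- A[1, i, ] * x[1, ] + A[2, i, ] * x[2, ] + A[3, i, ] * x[3, ]
  y
}

.cross3 <- function(a, b) {
  rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
        a[3, ] * b[1, ] - a[1, ] * b[3, ],
        a[1, ] * b[2, ] - a[2, ] * b[1, ])
}

# Per-sample log map for small relative rotations (3 x 3 x N -> 3 x N).
.rotarr_log_small <- function(C) {
  tr <- C[1, 1, ] + C[2, 2, ] + C[3, 3, ]
  cth <- pmin(pmax((tr - 1) / 2, -1), 1)
  th <- acos(cth)
  f <- ifelse(th < 1e-7, 1, th / sin(th))
  0.5 * rbind(f * (C[3, 2, ] - C[2, 3, ]),
              f * (C[1, 3, ] - C[3, 1, ]),
              f * (C[2, 1, ] - C[1, 2, ]))
}

# ---- rigid-body motion composition -----------------------------------------
# A "motion" is list(R = 3x3xN, w = 3xN, al = 3xN): orientation plus body-frame
# angular velocity and acceleration.

.motion_identity <- function(n) {
  R <- array(0, c(3, 3, n)); R[1, 1, ] <- R[2, 2, ] <- R[3, 3, ] <- 1
  list(R = R, w = matrix(0, 3, n), al = matrix(0, 3, n))
}

.motion_axis <- function(axis, sig) {
  list(R = .rots_axis(axis, sig$q),
       w = outer(axis, sig$qd),
       al = outer(axis, sig$qdd))
}

.compose_motion <- function(m1, m2) {
  w1r <- .rotarr_tvec(m2$R, m1$w)
  list(R = .rotarr_mul(m1$R, m2$R),
       w = w1r + m2$w,
       al = .rotarr_tvec(m2$R, m1$al) - .cross3(m2$w, w1r) + m2$al)
}

.compose_motion_static <- function(m1, R0) {
  list(R = .rotarr_mulc(m1$R, R0),
       w = t(R0) %*% m1$w,
       al = t(R0) %*% m1$al)
}

# Point kinematics of `origin + R d` for static body-frame offset d.
.attach_point <- function(motion, kin, d) {
  wxd <- .cross3(motion$w, matrix(d, 3, ncol(kin$p)))
  list(p = kin$p + .rotarr_vec(motion$R, d),
       v = kin$v + .rotarr_vec(motion$R, wxd),
       a = kin$a + .rotarr_vec(motion$R,
             .cross3(motion$al, matrix(d, 3, ncol(kin$p))) +
             .cross3(motion$w, wxd)))
}

.rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
.rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# ---- skeleton --------------------------------------------------------------

#' Sample a ground-truth skeleton
#'
#' Draws segment lengths from the packaged anthropometric priors (rejection
#' sampling inside the hard windows), cross-leg discrepancies from their
#' population stds, knee-axis/segment angles from the per-side priors
#' (within 3 sigma), and randomizes the IMU mounting poses on each segment
#' (vertical position and transverse-plane placement on the limb, plus a
#' random mounting tilt). Deterministic given `seed`.
#'
#' The knee axis points to the subject's right. Because the sampled
#' axis-femur and axis-tibia angles differ, the anatomical femur/tibia frames
#' are tilted in the sagittal plane relative to the straight-leg line by
#' angles `beta` chosen so both sampled angles hold simultaneously.
#'
#' @param config optional overrides: `max_tilt_deg` (mounting tilt bound,
#'   default 20), `priors` (see [default_anthro_priors()]).
#' @param seed integer seed.
#' @return list of class `"skeleton_truth"`.
#' @export
make_skeleton <- function(config = list(), seed = 1) {
  priors <- config$priors
  if (is.null(priors)) priors <- default_anthro_priors()
  max_tilt <- config$max_tilt_deg
  if (is.null(max_tilt)) max_tilt <- 20
  .with_seed(seed, function() {
    rnorm_win <- function(mu, sig, lo, hi) {
      repeat {
        x <- rnorm(1, mu, sig)
        if (x >= lo && x <= hi) return(x)
      }
    }
    len <- priors$lengths
    fem <- len[len$name == "femur", ]
    tib <- len[len$name == "tibia", ]
    hip <- len[len$name == "femoral_head_separation", ]
    disc <- priors$discrepancy
    L_fr <- rnorm_win(fem$mu, fem$sigma, fem$lmin, fem$lmax)
    L_fl <- rnorm_win(L_fr, disc$sigma[disc$name == "femur"], fem$lmin, fem$lmax)
    L_tr <- rnorm_win(tib$mu, tib$sigma, tib$lmin, tib$lmax)
    L_tl <- rnorm_win(L_tr, disc$sigma[disc$name == "tibia"], tib$lmin, tib$lmax)
    hw <- rnorm_win(hip$mu, hip$sigma, max(hip$lmin, 0.12), hip$lmax)

    axs <- priors$axis_segment
    ang <- function(seg, side) {
      r <- axs[axs$segment == seg & axs$side == side, ]
      rnorm_win(r$mu_deg, r$sigma_deg, r$mu_deg - 3 * r$sigma_deg,
                r$mu_deg + 3 * r$sigma_deg)
    }
    th <- list(fr = ang("femur", "right"), tr = ang("tibia", "right"),
               fl = ang("femur", "left"), tl = ang("tibia", "left"))
    # Hinge-axis elevation from the IMU/leg x-axis (sagittal plane) so the
    # axis makes the sampled angle with the hip-knee line, and tibia-line
    # bend (tibiofemoral angle) so it also makes the sampled angle with the
    # knee-ankle line.
    tilt <- function(th_f, th_t) {
      list(delta = (90 - th_f) * pi / 180, eta = (th_t - th_f) * pi / 180)
    }
    kr <- tilt(th$fr, th$tr)
    kl <- tilt(th$fl, th$tl)

    rand_rot <- function() {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      rot_exp(ax * runif(1, 0, max_tilt * pi / 180))
    }
    jit <- function(s) runif(3, -s, s)
    thigh_mount <- function(side_sign, L) {
      psi <- runif(1, -pi / 3, pi / 3)
      c(side_sign * 0.06 * cos(psi), 0.06 * sin(psi), -runif(1, 0.35, 0.65) * L)
    }
    shank_mount <- function(side_sign, L) {
      psi <- runif(1, -pi / 3, pi / 3)
      c(side_sign * 0.045 * cos(psi), 0.045 * sin(psi), -runif(1, 0.3, 0.6) * L)
    }
    mounts <- list(
      list(seg = "pelvis", d = c(0, -0.09, 0.15) + jit(0.01), R = rand_rot()),
      list(seg = "femur_r", d = thigh_mount(1, L_fr), R = rand_rot()),
      list(seg = "tibia_r", d = shank_mount(1, L_tr), R = rand_rot()),
      list(seg = "foot_r", d = c(0, 0.06, -0.04) + jit(0.005), R = rand_rot()),
      list(seg = "femur_l", d = thigh_mount(-1, L_fl), R = rand_rot()),
      list(seg = "tibia_l", d = shank_mount(-1, L_tl), R = rand_rot()),
      list(seg = "foot_l", d = c(0, 0.06, -0.04) + jit(0.005), R = rand_rot())
    )
    structure(list(
      femur = c(right = L_fr, left = L_fl),
      tibia = c(right = L_tr, left = L_tl),
      hip_width = hw,
      axis_angles_deg = th,
      knee_geom = list(right = kr, left = kl),
      mounts = mounts, seed = seed
    ), class = "skeleton_truth")
  })
}

# ---- motion script ---------------------------------------------------------

#' Script the calibration motion profile
#'
#' Builds the ordered primitive list of the lower-body excitation routine:
#' per-ankle flexion/extension cycles and foot circles, per-knee flexion
#' swings of at least 90 degrees, per-hip flexion/extension, ab/adduction
#' and internal/external rotation, then torso bend, twist and side bend
#' (realized as pelvis motion). Every lower-body degree of freedom receives
#' at least three repetitions of excitation. Amplitudes get a small
#' seed-driven jitter (within 10 percent) to vary trials.
#'
#' @param duration total profile duration (s), at least 30.
#' @param seed optional integer seed for the amplitude jitter.
#' @return data.frame of class `"motion_script"` with one row per primitive:
#'   joint, side, dof, type (`pulse`/`osc`/`circle`), amplitude (deg),
#'   reps, t0, t1.
#' @export
script_motion_profile <- function(duration = 60, seed = NULL) {
  if (duration < 30)
    stop("duration must be at least 30 s to fit the motion profile")
  base <- data.frame(
    joint = c("ankle", "ankle", "ankle", "ankle", "knee", "knee",
              "hip", "hip", "hip", "hip", "hip", "hip",
              "pelvis", "pelvis", "pelvis"),
    side = c("right", "right", "left", "left", "right", "left",
             "right", "right", "right", "left", "left", "left",
             "both", "both", "both"),
    dof = c("fe", "circle", "fe", "circle", "flex", "flex",
            "fe", "ab", "rot", "fe", "ab", "rot",
            "bend", "twist", "side"),
    type = c("pulse", "circle", "pulse", "circle", "pulse", "pulse",
             "pulse", "pulse", "osc", "pulse", "pulse", "osc",
             "pulse", "osc", "osc"),
    amplitude = c(25, 12, 25, 12, -100, -100,
                  55, -30, 30, 55, 30, 30,
                  30, 35, 20),
    reps = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  jitter <- .with_seed(seed, function() {
    if (is.null(seed)) rep(1, nrow(base)) else runif(nrow(base), 0.9, 1.1)
  })
  base$amplitude <- base$amplitude * jitter
  win <- duration / nrow(base)
  base$t0 <- (seq_len(nrow(base)) - 1) * win
  base$t1 <- base$t0 + win
  structure(base, class = c("motion_script", "data.frame"),
            duration = duration, seed = seed)
}

# ---- forward kinematics ----------------------------------------------------

.script_signal <- function(script, n, t, joint, side, dof) {
  sig <- .zero_sig(n)
  rows <- script[script$joint == joint & script$side == side & script$dof == dof, ]
  d2r <- pi / 180
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    s <- switch(r$type,
      pulse = .pulse_train(t, r$t0, r$t1, r$reps, r$amplitude * d2r),
      osc = .osc_train(t, r$t0, r$t1, r$reps, r$amplitude * d2r),
      circle = .pulse_train(t, r$t0, r$t1, r$reps, r$amplitude * d2r))
    sig <- .add_sig(sig, s)
  }
  sig
}

.circle_signals <- function(script, n, t, side) {
  rows <- script[script$joint == "ankle" & script$side == side &
                   script$dof == "circle", ]
  sx <- .zero_sig(n); sy <- .zero_sig(n)
  d2r <- pi / 180
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    sx <- .add_sig(sx, .osc_train(t, r$t0, r$t1, r$reps, r$amplitude * d2r, 0))
    sy <- .add_sig(sy, .osc_train(t, r$t0, r$t1, r$reps, r$amplitude * d2r, pi / 2))
  }
  list(x = sx, y = sy)
}

#' Generate exact IMU trajectories from a skeleton and motion script
#'
#' Realizes the rigid-body chain (pelvis root with 6-DOF sway, 3-DOF hips
#' and ankles, hinge knees about the sampled tilted axes) at the given rate.
#' Orientation, angular velocity, angular acceleration, position, velocity
#' and linear acceleration of all seven IMUs are propagated analytically, so
#' joint-center coherence holds to machine precision and the relative
#' angular velocity across each knee is exactly parallel to the true axis.
#'
#' @param skeleton a [make_skeleton()] result.
#' @param script a [script_motion_profile()] result.
#' @param rate sample rate (Hz), at least 50.
#' @param sway include the small continuous 6-DOF pelvis sway (set `FALSE`
#'   for strictly scripted motion, e.g. static scenes).
#' @return list of class `"truth_trajectory"`.
#' @export
forward_kinematics <- function(skeleton, script, rate = 200, sway = TRUE) {
  stopifnot(rate >= 50)
  duration <- attr(script, "duration")
  n <- as.integer(round(duration * rate)) + 1L
  t <- seq(0, by = 1 / rate, length.out = n)
  d2r <- pi / 180

  # pelvis root: scripted torso primitives + small continuous sway
  env <- .bump(t / duration)
  if (!sway) env <- list(w = numeric(n), wp = numeric(n), wpp = numeric(n))
  sway_rot <- function(A_deg, f, ph) {
    om <- 2 * pi * f
    s <- sin(om * t + ph) - sin(ph)  # zero at t = 0
    list(q = A_deg * d2r * env$w * s,
         qd = A_deg * d2r * (env$wp / duration * s + env$w * om * cos(om * t + ph)),
         qdd = A_deg * d2r * (env$wpp / duration^2 * s +
                 2 * env$wp / duration * om * cos(om * t + ph) -
                 env$w * om^2 * sin(om * t + ph)))
  }
  bend <- .add_sig(.script_signal(script, n, t, "pelvis", "both", "bend"),
                   sway_rot(2, 0.31, 0.4))
  twist <- .add_sig(.script_signal(script, n, t, "pelvis", "both", "twist"),
                    sway_rot(2, 0.23, 1.1))
  side <- .add_sig(.script_signal(script, n, t, "pelvis", "both", "side"),
                   sway_rot(2, 0.27, 2.3))
  pelvisM <- .compose_motion(.compose_motion(
    .motion_axis(c(1, 0, 0), bend), .motion_axis(c(0, 0, 1), twist)),
    .motion_axis(c(0, 1, 0), side))

  sway_pos <- function(A, f, ph) {
    om <- 2 * pi * f
    list(p = A * env$w * (sin(om * t + ph) - sin(ph)),
         v = A * (env$wp / duration * (sin(om * t + ph) - sin(ph)) +
                    env$w * om * cos(om * t + ph)),
         a = A * (env$wpp / duration^2 * (sin(om * t + ph) - sin(ph)) +
                    2 * env$wp / duration * om * cos(om * t + ph) -
                    env$w * om^2 * sin(om * t + ph)))
  }
  sx <- sway_pos(0.02, 0.27, 0.0); sy <- sway_pos(0.02, 0.34, 0.9)
  sz <- sway_pos(0.012, 0.41, 1.7)
  base_h <- skeleton$femur[["right"]] + skeleton$tibia[["right"]] + 0.08
  pelvis_kin <- list(p = rbind(sx$p, sy$p, base_h + sz$p),
                     v = rbind(sx$v, sy$v, sz$v),
                     a = rbind(sx$a, sy$a, sz$a))

  leg <- function(sside) {
    sgn <- if (sside == "right") 1 else -1
    suffix <- if (sside == "right") "r" else "l"
    L_f <- skeleton$femur[[sside]]; L_t <- skeleton$tibia[[sside]]
    geom <- skeleton$knee_geom[[sside]]
    hip_c <- c(sgn * skeleton$hip_width / 2, 0, 0)
    hip_kin <- .attach_point(pelvisM, pelvis_kin, hip_c)
    hipM <- .compose_motion(pelvisM, .compose_motion(.compose_motion(
      .motion_axis(c(1, 0, 0), .script_signal(script, n, t, "hip", sside, "fe")),
      .motion_axis(c(0, 1, 0), .script_signal(script, n, t, "hip", sside, "ab"))),
      .motion_axis(c(0, 0, 1), .script_signal(script, n, t, "hip", sside, "rot"))))
    knee_kin <- .attach_point(hipM, hip_kin, c(0, 0, -L_f))
    axis_leg <- c(cos(geom$delta), 0, sin(geom$delta))
    knee_sig <- .script_signal(script, n, t, "knee", sside, "flex")
    tibM <- .compose_motion(hipM, .motion_axis(axis_leg, knee_sig))
    u_t <- c(-sin(geom$eta), 0, cos(geom$eta))  # knee->ankle proximal dir
    ankle_kin <- .attach_point(tibM, knee_kin, -L_t * u_t)
    circ <- .circle_signals(script, n, t, sside)
    footM <- .compose_motion(tibM, .compose_motion(
      .motion_axis(c(1, 0, 0),
                   .add_sig(.script_signal(script, n, t, "ankle", sside, "fe"),
                            circ$x)),
      .motion_axis(c(0, 1, 0), circ$y)))
    list(hipM = hipM, tibM = tibM, footM = footM,
         hip_kin = hip_kin, knee_kin = knee_kin, ankle_kin = ankle_kin,
         knee_sig = knee_sig, axis_leg = axis_leg, u_t = u_t, geom = geom,
         suffix = suffix)
  }
  R <- leg("right"); L <- leg("left")

  seg_motion <- list(pelvis = pelvisM, femur_r = R$hipM, tibia_r = R$tibM,
                     foot_r = R$footM, femur_l = L$hipM, tibia_l = L$tibM,
                     foot_l = L$footM)
  seg_kin <- list(pelvis = pelvis_kin, femur_r = R$hip_kin, tibia_r = R$knee_kin,
                  foot_r = R$ankle_kin, femur_l = L$hip_kin,
                  tibia_l = L$knee_kin, foot_l = L$ankle_kin)

  imus <- vector("list", 7)
  for (i in 1:7) {
    m <- skeleton$mounts[[i]]
    sm <- seg_motion[[m$seg]]
    kin <- .attach_point(sm, seg_kin[[m$seg]], m$d)
    mot <- .compose_motion_static(sm, m$R)
    imus[[i]] <- list(R = mot$R, w = mot$w, alpha = mot$al,
                      p = kin$p, v = kin$v, a = kin$a)
  }

  joints <- list(rh = R$hip_kin$p, rk = R$knee_kin$p, ra = R$ankle_kin$p,
                 lh = L$hip_kin$p, lk = L$knee_kin$p, la = L$ankle_kin$p)

  # true static axes (IMU frames) and IMU-to-joint offsets, from t = 0
  axis_in_imu <- function(imu_idx, axis_leg)
    as.numeric(t(skeleton$mounts[[imu_idx]]$R) %*% axis_leg)
  axes_true <- cbind(axis_in_imu(2, R$axis_leg), axis_in_imu(3, R$axis_leg),
                     axis_in_imu(5, L$axis_leg), axis_in_imu(6, L$axis_leg))
  colnames(axes_true) <- c("r2", "r3", "r5", "r6")

  off <- function(imu_idx, joint)
    as.numeric(t(imus[[imu_idx]]$R[, , 1]) %*%
                 (joints[[joint]][, 1] - imus[[imu_idx]]$p[, 1]))
  offs_true <- cbind(off(1, "rh"), off(1, "lh"), off(2, "rh"), off(2, "rk"),
                     off(3, "rk"), off(3, "ra"), off(4, "ra"), off(5, "lh"),
                     off(5, "lk"), off(6, "lk"), off(6, "la"), off(7, "la"))
  colnames(offs_true) <- .offset_names()

  # Anatomical segment orientations via the same leg-coordinate-system
  # construction the estimator uses: x from the hinge axis, z the
  # joint-center line (both static in the segment motion frames).
  segments <- list(
    pelvis = pelvisM$R,
    femur_r = .rotarr_mulc(R$hipM$R, t(build_lcs(R$axis_leg, c(0, 0, 1)))),
    tibia_r = .rotarr_mulc(R$tibM$R, t(build_lcs(R$axis_leg, R$u_t))),
    femur_l = .rotarr_mulc(L$hipM$R, t(build_lcs(L$axis_leg, c(0, 0, 1)))),
    tibia_l = .rotarr_mulc(L$tibM$R, t(build_lcs(L$axis_leg, L$u_t))))

  ka_r <- knee_angles(segments$femur_r, segments$tibia_r, side = "right")
  ka_l <- knee_angles(segments$femur_l, segments$tibia_l, side = "left")

  structure(list(
    t = t, rate = rate, duration = duration, n = n,
    imus = imus, joints = joints, segments = segments,
    axes_true = axes_true, offs_true = offs_true,
    knee_q_deg = list(right = R$knee_sig$q / d2r, left = L$knee_sig$q / d2r),
    knee_angles_true = list(right = ka_r, left = ka_l),
    skeleton = skeleton, script = script
  ), class = "truth_trajectory")
}

.offset_names <- function() {
  c("s1rh", "s1lh", "s2rh", "s2rk", "s3rk", "s3ra",
    "s4ra", "s5lh", "s5lk", "s6lk", "s6la", "s7la")
}

# ---- soft-tissue perturbation ----------------------------------------------

#' Perturb IMU mounting poses to emulate soft-tissue artifact
#'
#' Adds a small zero-mean oscillation to each IMU's mounting pose: a
#' translation of amplitude `amplitude_mm` along a fixed random IMU-frame
#' direction and a rotation of amplitude `amplitude_deg` about a fixed random
#' axis, both sinusoidal at `frequency` (snapped to an integer number of
#' cycles over the trajectory so the perturbation is exactly zero-mean).
#' Kinematic quantities (velocity, acceleration, angular velocity) are
#' updated analytically, so the perturbed trajectory remains exactly
#' self-consistent as a rigid-body motion; what breaks -- deliberately -- is
#' the static IMU-to-joint-center and static-axis assumption.
#'
#' @param truth a [forward_kinematics()] result.
#' @param amplitude_mm translation amplitude (mm).
#' @param amplitude_deg rotation amplitude (deg).
#' @param frequency oscillation frequency (Hz).
#' @param seed integer seed for directions and phases.
#' @return perturbed `"truth_trajectory"` (ground-truth statics unchanged).
#' @export
perturb_soft_tissue <- function(truth, amplitude_mm = 5, amplitude_deg = 1,
                                frequency = 1, seed = NULL) {
  stopifnot(amplitude_mm >= 0, amplitude_deg >= 0)
  if (amplitude_mm == 0 && amplitude_deg == 0) return(truth)
  t <- truth$t
  dur <- truth$duration
  f <- max(1, round(frequency * dur)) / dur
  om <- 2 * pi * f
  .with_seed(seed, function() {
    for (i in seq_along(truth$imus)) {
      imu <- truth$imus[[i]]
      nT <- length(t)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      ph <- runif(1, 0, 2 * pi)
      A <- amplitude_mm / 1000
      s <- sin(om * t + ph)   # integer cycles: exactly zero-mean
      d <- outer(u * A, rep(1, nT)) * rep(s, each = 3)
      dd <- outer(u * A * om, rep(1, nT)) * rep(cos(om * t + ph), each = 3)
      ddd <- outer(u * A * om^2, rep(1, nT)) * rep(-sin(om * t + ph), each = 3)
      wxd <- .cross3(imu$w, d)
      p2 <- imu$p + .rotarr_vec(imu$R, d)
      v2 <- imu$v + .rotarr_vec(imu$R, wxd + dd)
      a2 <- imu$a + .rotarr_vec(imu$R,
        .cross3(imu$alpha, d) + .cross3(imu$w, wxd) +
          2 * .cross3(imu$w, dd) + ddd)

      e <- rnorm(3); e <- e / sqrt(sum(e^2))
      ph2 <- runif(1, 0, 2 * pi)
      Ar <- amplitude_deg * pi / 180
      eps <- list(q = Ar * sin(om * t + ph2),
                  qd = Ar * om * cos(om * t + ph2),
                  qdd = -Ar * om^2 * sin(om * t + ph2))
      mot2 <- .compose_motion(list(R = imu$R, w = imu$w, al = imu$alpha),
                              .motion_axis(e, eps))
      truth$imus[[i]] <- list(R = mot2$R, w = mot2$w, alpha = mot2$al,
                              p = p2, v = v2, a = a2)
    }
    truth$soft_tissue <- list(amplitude_mm = amplitude_mm,
                              amplitude_deg = amplitude_deg, frequency = f)
    truth
  })
}

# ---- measurement synthesis -------------------------------------------------

#' Synthesize IMU measurement streams from a truth trajectory
#'
#' Applies the measurement model: gyro = body rate + bias + white noise,
#' accelerometer = specific force (body frame) + bias + white noise, with
#' biases evolving as a random walk. Discrete white-noise stds are the
#' continuous densities scaled by `1/sqrt(dt)`.
#'
#' Two discretizations of the body rate are available. `"discrete"` (the
#' default) emits the exact per-interval rates
#' `Log(R_k^T R_(k+1)) / dt` and velocity differences, so the package's
#' first-order integrator reproduces the continuous truth exactly in the
#' noise-free limit -- which makes noise-free recovery studies meaningful.
#' `"sampled"` emits instantaneous rates and specific forces at the sample
#' instants.
#'
#' @param truth a [forward_kinematics()] (optionally soft-tissue-perturbed)
#'   result.
#' @param noise a [noise_spec()]; its `dt` must match the truth rate.
#' @param seed integer seed.
#' @param noisy if `FALSE`, biases and white noise are omitted.
#' @param mode `"discrete"` or `"sampled"`.
#' @param bias0_g,bias0_a stds of the initial bias draw (rad/s, m/s^2).
#' @return list of class `"imu_streams"`: seven streams with `t`, `gyro`
#'   (N x 3) and `accel` (N x 3); true per-sample biases are attached as
#'   attribute `"bias_true"`.
#' @export
synthesize_imu <- function(truth, noise = noise_spec(), seed = NULL,
                           noisy = TRUE, mode = c("discrete", "sampled"),
                           bias0_g = 0.005, bias0_a = 0.02) {
  mode <- match.arg(mode)
  dt <- 1 / truth$rate
  if (abs(dt - noise$dt) > 1e-12)
    stop("noise$dt does not match the truth sample rate")
  nT <- truth$n
  g <- noise$g
  .with_seed(seed, function() {
    streams <- vector("list", 7)
    biases <- vector("list", 7)
    for (i in 1:7) {
      imu <- truth$imus[[i]]
      if (mode == "discrete") {
        rel <- .rotarr_tmul(imu$R[, , 1:(nT - 1), drop = FALSE],
                            imu$R[, , 2:nT, drop = FALSE])
        gyro <- cbind(.rotarr_log_small(rel) / dt, imu$w[, nT])
        dv <- (imu$v[, 2:nT, drop = FALSE] - imu$v[, 1:(nT - 1), drop = FALSE]) / dt
        acc_n <- cbind(dv, imu$a[, nT])
        accel <- .rotarr_tvec(imu$R, acc_n - g)
      } else {
        gyro <- imu$w
        accel <- .rotarr_tvec(imu$R, imu$a - g)
      }
      if (noisy) {
        b0 <- c(rnorm(3, 0, bias0_g), rnorm(3, 0, bias0_a))
        walk <- rbind(matrix(rnorm(3 * nT, 0, noise$sigma_bw_g * sqrt(dt)), 3),
                      matrix(rnorm(3 * nT, 0, noise$sigma_bw_a * sqrt(dt)), 3))
        b <- b0 + t(apply(walk, 1, cumsum))
        gyro <- gyro + b[1:3, ] +
          matrix(rnorm(3 * nT, 0, noise$sigma_w / sqrt(dt)), 3)
        accel <- accel + b[4:6, ] +
          matrix(rnorm(3 * nT, 0, noise$sigma_a / sqrt(dt)), 3)
        biases[[i]] <- b
      } else {
        biases[[i]] <- matrix(0, 6, nT)
      }
      streams[[i]] <- list(t = truth$t, gyro = t(gyro), accel = t(accel))
    }
    structure(streams, class = "imu_streams", bias_true = biases, mode = mode)
  })
}

#' One-call synthetic dataset
#'
#' Samples a skeleton, scripts the motion profile, runs forward kinematics,
#' optionally applies soft-tissue perturbation, and synthesizes measurement
#' streams. All randomness is derived from `seed`.
#'
#' @param duration profile duration (s).
#' @param seed integer master seed.
#' @param noise a [noise_spec()].
#' @param noisy include sensor noise and biases.
#' @param soft_tissue_mm,soft_tissue_deg,soft_tissue_hz soft-tissue
#'   perturbation parameters (0 disables).
#' @param rate sample rate (Hz).
#' @param mode measurement discretization, see [synthesize_imu()].
#' @return list with `truth` (unperturbed ground truth), `streams`,
#'   `skeleton`, `script`.
#' @export
simulate_dataset <- function(duration = 60, seed = 1, noise = noise_spec(),
                             noisy = TRUE, soft_tissue_mm = 0,
                             soft_tissue_deg = 0, soft_tissue_hz = 1,
                             rate = 200, mode = "discrete") {
  noise$dt <- 1 / rate
  skeleton <- make_skeleton(seed = seed)
  script <- script_motion_profile(duration, seed = seed + 1L)
  truth <- forward_kinematics(skeleton, script, rate)
  meas_truth <- truth
  if (soft_tissue_mm > 0 || soft_tissue_deg > 0)
    meas_truth <- perturb_soft_tissue(truth, soft_tissue_mm, soft_tissue_deg,
                                      soft_tissue_hz, seed = seed + 2L)
  streams <- synthesize_imu(meas_truth, noise, seed = seed + 3L,
                            noisy = noisy, mode = mode)
  list(truth = truth, streams = streams, skeleton = skeleton, script = script)
}
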