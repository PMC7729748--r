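# Post-hoc anatomy: leg coordinate systems, knee-axis sign disambiguation,
# Grood-Suntay joint angles, and evaluation metrics.

#' Orthonormal leg coordinate system
#'
#' Builds a rotation whose rows are the anatomical axes expressed in the
#' input frame: the proximal direction `z` is kept exactly (third row), the
#' right-pointing direction is `x` projected orthogonal to `z` (first row),
#' and the anterior direction is their cross product (second row):
#' rows `((z x x) x z, z x x, z)`, each normalized. The inputs need not be
#' orthogonal or unit length.
#'
#' @param x approximate right-pointing direction (e.g. the knee axis).
#' @param z proximal direction.
#' @return 3x3 proper rotation.
#' @export
build_lcs <- function(x, z) {
  x <- as.numeric(x); z <- as.numeric(z)
  stopifnot(length(x) == 3, length(z) == 3)
  nz <- sqrt(sum(z^2)); nx <- sqrt(sum(x^2))
  if (nz == 0 || nx == 0) stop("build_lcs: zero-length input")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  y <- cr(z, x)
  if (sqrt(sum(y^2)) < 1e-12 * nz * nx)
    stop("build_lcs: x and z are parallel")
  xo <- cr(y, z)
  R <- rbind(xo / sqrt(sum(xo^2)), y / sqrt(sum(y^2)), z / nz)
  dimnames(R) <- NULL
  R
}

#' Static IMU-to-anatomical-segment orientation
#'
#' `R_A^A'` with rows the anatomical axes in the IMU frame, from the
#' estimated knee axis and the segment proximal vector
#' `(s_prox - s_dist)`. The anatomical orientation trajectory follows as
#' `R^N_A' = R^N_A %*% t(R_A^A')`.
#'
#' @param r unit knee axis in the IMU frame.
#' @param s_prox,s_dist IMU-frame offsets to the proximal/distal joint
#'   centers (m).
#' @return 3x3 rotation `R_A^A'`.
#' @export
segment_orientation <- function(r, s_prox, s_dist) {
  w <- as.numeric(s_prox) - as.numeric(s_dist)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("zero-length segment")
  build_lcs(r, w / nw)
}

#' Grood-Suntay knee angles
#'
#' Joint-coordinate-system decomposition of the relative orientation between
#' femur and tibia: body-fixed axis e1 = femoral x (flexion/extension),
#' body-fixed axis e3 = tibial z (internal/external rotation), floating axis
#' e2 = e3 x e1. Equivalent to the Cardan x-y-z factorization of
#' `t(R_femur) %*% R_tibia`. Flexion is negative (extension positive), so
#' knee range of motion falls in roughly [+10, -150] degrees.
#' Ab/adduction is the complement of the angle between e1 and e3; its sign
#' and the rotation sign are mirrored for the left side so adduction and
#' internal rotation are positive on both sides.
#'
#' @param R_femur,R_tibia 3x3xN arrays (or single 3x3 matrices) of
#'   navigation-frame anatomical orientations.
#' @param side `"right"` or `"left"`.
#' @return data.frame of class `"knee_angle_series"` with columns `flexion`,
#'   `rotation`, `adduction` (degrees). A `gimbal` attribute flags frames
#'   with |e1 . e3| > 0.999.
#' @export
knee_angles <- function(R_femur, R_tibia, side = c("right", "left")) {
  side <- match.arg(side)
  if (length(dim(R_femur)) == 2) R_femur <- array(R_femur, c(3, 3, 1))
  if (length(dim(R_tibia)) == 2) R_tibia <- array(R_tibia, c(3, 3, 1))
  stopifnot(dim(R_femur)[3] == dim(R_tibia)[3])
  C <- .rotarr_tmul(R_femur, R_tibia)
  r2d <- 180 / pi
  flex <- atan2(-C[2, 3, ], C[3, 3, ]) * r2d
  s13 <- pmin(pmax(C[1, 3, ], -1), 1)
  b <- asin(s13) * r2d
  gam <- atan2(-C[1, 2, ], C[1, 1, ]) * r2d
  sgn <- if (side == "right") 1 else -1
  out <- data.frame(flexion = flex, rotation = sgn * gam,
                    adduction = sgn * b)
  structure(out, class = c("knee_angle_series", "data.frame"),
            side = side, gimbal = abs(s13) > 0.999)
}

# Compose a relative rotation from a Grood-Suntay angle triple (degrees);
# inverse of knee_angles() for one side. Used in round-trip tests.
gs_compose <- function(flexion, rotation, adduction, side = "right") {
  sgn <- if (side == "right") 1 else -1
  d2r <- pi / 180
  .rotx(flexion * d2r) %*% .roty(sgn * adduction * d2r) %*%
    .rotz(sgn * rotation * d2r)
}

# ---- solution accessors ----------------------------------------------------

# 3 x 3 x M orientation trajectory of IMU s from a solution.
.sol_R <- function(solution, s) {
  idx <- seq(s, by = 7, length.out = solution$M)
  solution$values$R[, , idx, drop = FALSE]
}

.sol_mat <- function(solution, field, s) {
  idx <- seq(s, by = 7, length.out = solution$M)
  solution$values[[field]][, idx, drop = FALSE]
}

# knee bookkeeping: axis column indices, flanking IMUs, offset columns
.knee_info <- function(side) {
  if (side == "right")
    list(ax_prox = 1L, ax_dist = 2L, imu_prox = 2L, imu_dist = 3L,
         o_fp = 3L, o_fd = 4L, o_tp = 5L, o_td = 6L)
  else
    list(ax_prox = 3L, ax_dist = 4L, imu_prox = 5L, imu_dist = 6L,
         o_fp = 8L, o_fd = 9L, o_tp = 10L, o_td = 11L)
}

.solution_knee_angles_one <- function(solution, side) {
  ki <- .knee_info(side)
  ax <- solution$values$axes
  offs <- solution$values$offs
  Rf_imu <- .sol_R(solution, ki$imu_prox)
  Rt_imu <- .sol_R(solution, ki$imu_dist)
  Rffp <- segment_orientation(ax[, ki$ax_prox], offs[, ki$o_fp], offs[, ki$o_fd])
  Rttp <- segment_orientation(ax[, ki$ax_dist], offs[, ki$o_tp], offs[, ki$o_td])
  knee_angles(.rotarr_mulc(Rf_imu, t(Rffp)), .rotarr_mulc(Rt_imu, t(Rttp)),
              side = side)
}

#' Disambiguate knee-axis signs
#'
#' The hinge residual is invariant under negation of either axis, giving
#' four equivalent-error sign combinations per leg. This post-hoc step makes
#' all axes point to the subject's right. Step 1: both axes of a knee are
#' rotated into the navigation frame at every keyframe; if the median
#' inter-axis angle exceeds 90 degrees the distal axis is flipped. Step 2:
#' the knee flexion series is computed; if its median exceeds +20 degrees
#' both axes must point left, so both are flipped and the angle recomputed.
#' The procedure is idempotent. A median inter-axis angle within 1e-6 of
#' exactly 90 degrees is genuinely ambiguous and raises an error.
#'
#' @param solution an estimator solution (see [optimize_graph()]).
#' @return the solution with corrected axes.
#' @export
disambiguate_axes <- function(solution) {
  r2d <- 180 / pi
  for (side in c("right", "left")) {
    ki <- .knee_info(side)
    rA <- solution$values$axes[, ki$ax_prox]
    rB <- solution$values$axes[, ki$ax_dist]
    aA <- .rotarr_vec(.sol_R(solution, ki$imu_prox), rA)
    aB <- .rotarr_vec(.sol_R(solution, ki$imu_dist), rB)
    ang <- acos(pmin(pmax(colSums(aA * aB), -1), 1)) * r2d
    med <- stats::median(ang)
    if (abs(med - 90) < 1e-6)
      stop("disambiguate_axes: median inter-axis angle is 90 degrees (",
           side, " knee); axis direction is genuinely ambiguous")
    if (med > 90)
      solution$values$axes[, ki$ax_dist] <- -solution$values$axes[, ki$ax_dist]
    ka <- .solution_knee_angles_one(solution, side)
    if (stats::median(ka$flexion) > 20) {
      solution$values$axes[, ki$ax_prox] <- -solution$values$axes[, ki$ax_prox]
      solution$values$axes[, ki$ax_dist] <- -solution$values$axes[, ki$ax_dist]
    }
  }
  solution$disambiguated <- TRUE
  solution
}

#' Derive disambiguated knee angles from a solution
#'
#' Runs [disambiguate_axes()] (unless already done), constructs the
#' anatomical femur/tibia orientation trajectories from the estimated axes
#' and joint-center offsets, and decomposes them with [knee_angles()].
#'
#' @param solution an estimator solution.
#' @return list with `right` and `left` [knee_angles()] series, the keyframe
#'   times `t`, and the (possibly axis-corrected) `solution`.
#' @export
derive_knee_angles <- function(solution) {
  if (!isTRUE(solution$disambiguated)) solution <- disambiguate_axes(solution)
  list(right = .solution_knee_angles_one(solution, "right"),
       left = .solution_knee_angles_one(solution, "left"),
       t = solution$t, solution = solution)
}

# ---- metrics ---------------------------------------------------------------

#' RMSE of inter-IMU distance
#'
#' Compares the time series of the norm distance between two IMUs in the
#' estimate against a reference: RMSE over keyframes of
#' `||p_A - p_B||_est - ||p_A - p_B||_ref`. Using norm distances makes the
#' metric invariant to the global position/heading gauge.
#'
#' @param est_a,est_b 3 x M estimated positions (m).
#' @param ref_a,ref_b 3 x M reference positions (m).
#' @return scalar RMSE in centimeters.
#' @export
distance_rmse <- function(est_a, est_b, ref_a, ref_b) {
  stopifnot(ncol(est_a) == ncol(est_b), ncol(ref_a) == ncol(ref_b))
  if (ncol(est_a) != ncol(ref_a)) stop("sequence length mismatch")
  d_est <- sqrt(colSums((est_a - est_b)^2))
  d_ref <- sqrt(colSums((ref_a - ref_b)^2))
  sqrt(mean((d_est - d_ref)^2)) * 100
}

#' RMSE and peak error between two angle series
#'
#' @param est,ref angle sequences (degrees), equal length.
#' @return list with `rmse` and `peak` (max absolute difference), degrees.
#' @export
angle_error_stats <- function(est, ref) {
  if (length(est) != length(ref)) stop("sequence length mismatch")
  d <- est - ref
  list(rmse = sqrt(mean(d^2)), peak = max(abs(d)))
}

# yaw/pitch/roll (Z-Y-X Euler) of a rotation array, degrees; 3 x N.
.euler_zyx <- function(Rarr) {
  if (length(dim(Rarr)) == 2) Rarr <- array(Rarr, c(3, 3, 1))
  r2d <- 180 / pi
  rbind(yaw = atan2(Rarr[2, 1, ], Rarr[1, 1, ]) * r2d,
        pitch = asin(pmin(pmax(-Rarr[3, 1, ], -1), 1)) * r2d,
        roll = atan2(Rarr[3, 2, ], Rarr[3, 3, ]) * r2d)
}

#' Evaluate a solution against synthetic ground truth
#'
#' Computes gauge-invariant recovery metrics at the keyframe instants:
#' knee flexion RMSE per side (estimated vs. true Grood-Suntay flexion),
#' pitch and roll RMSE per IMU, inter-IMU norm-distance RMSE per adjacent
#' pair, knee-axis angular error (up to sign), and joint-center offset
#' errors.
#'
#' @param solution an estimator solution.
#' @param truth the matching [forward_kinematics()] ground truth.
#' @return list of metric vectors (degrees / centimeters).
#' @export
evaluate_solution <- function(solution, truth) {
  M <- solution$M
  dec <- solution$decimation
  ki <- 1L + (0:(M - 1)) * dec
  stopifnot(max(ki) <= truth$n)
  ang <- derive_knee_angles(solution)

  flex <- c(
    right = angle_error_stats(ang$right$flexion,
                              truth$knee_angles_true$right$flexion[ki])$rmse,
    left = angle_error_stats(ang$left$flexion,
                             truth$knee_angles_true$left$flexion[ki])$rmse)
  peak <- c(
    right = angle_error_stats(ang$right$flexion,
                              truth$knee_angles_true$right$flexion[ki])$peak,
    left = angle_error_stats(ang$left$flexion,
                             truth$knee_angles_true$left$flexion[ki])$peak)

  pitch <- roll <- numeric(7)
  for (s in 1:7) {
    e_est <- .euler_zyx(.sol_R(solution, s))
    e_ref <- .euler_zyx(truth$imus[[s]]$R[, , ki, drop = FALSE])
    pitch[s] <- sqrt(mean((e_est["pitch", ] - e_ref["pitch", ])^2))
    roll[s] <- sqrt(mean((e_est["roll", ] - e_ref["roll", ])^2))
  }

  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(5, 6), c(6, 7))
  dist_cm <- apply(pairs, 1, function(pr)
    distance_rmse(.sol_mat(solution, "p", pr[1]), .sol_mat(solution, "p", pr[2]),
                  truth$imus[[pr[1]]]$p[, ki, drop = FALSE],
                  truth$imus[[pr[2]]]$p[, ki, drop = FALSE]))
  names(dist_cm) <- apply(pairs, 1, paste, collapse = "-")

  ax_est <- ang$solution$values$axes
  axis_err <- sapply(1:4, function(a) {
    cth <- abs(sum(ax_est[, a] * truth$axes_true[, a]))
    acos(min(1, cth)) * 180 / pi
  })
  names(axis_err) <- colnames(truth$axes_true)

  off_err <- sqrt(colSums((ang$solution$values$offs - truth$offs_true)^2)) * 100
  names(off_err) <- .offset_names()

  list(knee_flexion_rmse = flex, knee_flexion_peak = peak,
       pitch_rmse = pitch, roll_rmse = roll,
       distance_rmse_cm = dist_cm, axis_error_deg = axis_err,
       offset_error_cm = off_err)
}
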