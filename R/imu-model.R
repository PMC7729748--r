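#' Noise and discretization specification
#'
#' Collects the IMU stochastic model and the keyframing parameters used
#' throughout the estimator: continuous white-noise densities of the gyro and
#' accelerometer, bias random-walk densities, the covariances of the
#' keyframe angular-velocity, knee-hinge and joint-center residuals, gravity,
#' the sample period and the decimation (samples per keyframe interval).
#'
#' Scalar `sigma_g`, `sigma_K`, `sigma_j` are expanded to isotropic 3x3
#' covariances; full matrices may be supplied instead (e.g. fitted with
#' [fit_noise_covariance()]). Defaults are deliberately generic; simulation
#' studies should pass values consistent with the noise actually injected
#' (for instance `sigma_g = sigma_w / sqrt(dt)`, the discrete-time gyro noise
#' at the keyframe sample).
#'
#' @param sigma_w gyro white-noise density (rad/s/sqrt(Hz)).
#' @param sigma_a accelerometer white-noise density (m/s^2/sqrt(Hz)).
#' @param sigma_bw_g,sigma_bw_a bias random-walk densities (rad/s/sqrt(s),
#'   m/s^2/sqrt(s)).
#' @param sigma_g keyframe angular-velocity residual std (rad/s) or 3x3
#'   covariance.
#' @param sigma_K hinge residual std (rad/s) or 3x3 covariance.
#' @param sigma_j joint-center residual std (m) or 3x3 covariance.
#' @param g gravity vector in the navigation frame (m/s^2), z-up default.
#' @param dt sample period (s).
#' @param decimation samples preintegrated per keyframe interval.
#' @return list of class `"noise_spec"`.
#' @export
noise_spec <- function(sigma_w = 0.005, sigma_a = 0.05,
                       sigma_bw_g = 1e-4, sigma_bw_a = 1e-4,
                       sigma_g = 0.005, sigma_K = 0.05, sigma_j = 0.01,
                       g = c(0, 0, -9.81), dt = 1 / 200, decimation = 20L) {
  as_cov <- function(x, name) {
    if (is.matrix(x)) {
      stopifnot(all(dim(x) == c(3, 3)))
      if (max(abs(x - t(x))) > 1e-12 || any(eigen(x, TRUE)$values <= 0))
        stop(name, " covariance must be symmetric positive definite")
      x
    } else diag(3) * x^2
  }
  stopifnot(dt > 0, decimation >= 1, sigma_w > 0, sigma_a > 0,
            sigma_bw_g > 0, sigma_bw_a > 0, length(g) == 3)
  structure(list(
    sigma_w = sigma_w, sigma_a = sigma_a,
    sigma_bw_g = sigma_bw_g, sigma_bw_a = sigma_bw_a,
    Sigma_g = as_cov(sigma_g, "Sigma_g"),
    Sigma_K = as_cov(sigma_K, "Sigma_K"),
    Sigma_j = as_cov(sigma_j, "Sigma_j"),
    g = as.numeric(g), dt = dt, decimation = as.integer(decimation)
  ), class = "noise_spec")
}

# Whitener W with W %*% e unit-variance for covariance S: W = inv(lower chol).
.whitener <- function(S) {
  L <- t(chol(S))
  forwardsolve(L, diag(nrow(S)))
}

#' IMU state
#'
#' Per-keyframe state of one IMU: pose (orientation `R`, position `p`),
#' velocity `v`, instantaneous angular velocity `w` (body frame), and the
#' 6-dim bias `b` ordered (gyro, accel).
#'
#' @param R 3x3 rotation; @param p,v length-3; @param w length-3 (rad/s);
#' @param b length-6 bias (b_gyro, b_accel).
#' @return list of class `"imu_state"`.
#' @export
imu_state <- function(R = diag(3), p = c(0, 0, 0), v = c(0, 0, 0),
                      w = c(0, 0, 0), b = rep(0, 6)) {
  .check_rotation(R)
  stopifnot(length(p) == 3, length(v) == 3, length(w) == 3, length(b) == 6)
  structure(list(R = R, p = as.numeric(p), v = as.numeric(v),
                 w = as.numeric(w), b = as.numeric(b)), class = "imu_state")
}

#' Advance an IMU state by one measurement sample
#'
#' First-order (Euler) discretization of the strapdown kinematics: the
#' bias-corrected gyro advances the orientation through the exponential map,
#' and the bias-corrected specific force plus gravity advance velocity and
#' position. Noise does not enter here; it is accounted for in the residual
#' covariances.
#'
#' @param state an [imu_state()].
#' @param gyro,accel length-3 measurements (rad/s, m/s^2).
#' @param noise a [noise_spec()] (supplies `g` and `dt`).
#' @return the advanced [imu_state()].
#' @export
integrate_step <- function(state, gyro, accel, noise) {
  dt <- noise$dt
  g <- noise$g
  bg <- state$b[1:3]; ba <- state$b[4:6]
  acc <- as.numeric(state$R %*% (accel - ba))
  R2 <- state$R %*% rot_exp((gyro - bg) * dt)
  p2 <- state$p + state$v * dt + 0.5 * g * dt^2 + 0.5 * acc * dt^2
  v2 <- state$v + g * dt + acc * dt
  imu_state(project_rotation(R2), p2, v2, gyro - bg, state$b)
}

#' Preintegrate a window of IMU measurements
#'
#' Compounds all gyro/accelerometer samples between two keyframes into a
#' single relative-motion constraint: the gravity-free, frame-i-relative
#' orientation/velocity/position deltas, their 9x9 first-order covariance,
#' and the Jacobians of the deltas with respect to the gyro and accelerometer
#' biases (which allow first-order correction when the estimated bias moves
#' away from the linearization bias without re-integration).
#'
#' @param gyro,accel n x 3 matrices of measurements.
#' @param t optional timestamps; if given, uniformity is checked against
#'   `noise$dt` and a non-uniform step is reported with its index.
#' @param lin_bias length-6 linearization bias (gyro, accel).
#' @param noise a [noise_spec()].
#' @return list of class `"preintegrated_delta"` with elements `dR`, `dv`,
#'   `dp`, `cov`, `Linv` (whitener), `Jb` (9x6 bias Jacobian), `dT`, `n`,
#'   `lin_bias`.
#' @export
preintegrate <- function(gyro, accel, noise, lin_bias = rep(0, 6), t = NULL) {
  gyro <- rbind(gyro); accel <- rbind(accel)
  if (nrow(gyro) < 1) stop("preintegrate: need at least one measurement")
  stopifnot(ncol(gyro) == 3, ncol(accel) == 3, nrow(gyro) == nrow(accel))
  if (!is.null(t) && length(t) > 1) {
    steps <- diff(t)
    bad <- which(abs(steps - noise$dt) > 1e-6)
    if (length(bad))
      stop("non-uniform timestamps at index ", bad[1] + 1,
           " (step ", signif(steps[bad[1]], 6), " s)")
  }
  out <- preintegrate_cpp(t(gyro), t(accel), noise$dt,
                          lin_bias[1:3], lin_bias[4:6],
                          noise$sigma_w, noise$sigma_a)
  out$dv <- as.numeric(out$dv); out$dp <- as.numeric(out$dp)
  out$lin_bias <- as.numeric(out$lin_bias)
  class(out) <- "preintegrated_delta"
  out
}

# Bias-corrected deltas for a bias `b` near the linearization point.
.preint_corrected <- function(delta, b) {
  db <- b - delta$lin_bias
  dRc <- delta$dR %*% rot_exp(as.numeric(delta$Jb[1:3, 1:3] %*% db[1:3]))
  list(dR = dRc,
       dv = delta$dv + as.numeric(delta$Jb[4:6, ] %*% db),
       dp = delta$dp + as.numeric(delta$Jb[7:9, ] %*% db))
}

#' Predict the keyframe-j state implied by a preintegrated delta
#'
#' @param delta a [preintegrate()] result.
#' @param state_i [imu_state()] at the start of the window.
#' @param noise a [noise_spec()] (gravity).
#' @return [imu_state()] at the end of the window (angular velocity and bias
#'   carried over).
#' @export
preint_predict <- function(delta, state_i, noise) {
  cd <- .preint_corrected(delta, state_i$b)
  dT <- delta$dT
  g <- noise$g
  R_j <- state_i$R %*% cd$dR
  v_j <- state_i$v + g * dT + as.numeric(state_i$R %*% cd$dv)
  p_j <- state_i$p + state_i$v * dT + 0.5 * g * dT^2 +
    as.numeric(state_i$R %*% cd$dp)
  imu_state(project_rotation(R_j), p_j, v_j, state_i$w, state_i$b)
}

#' Preintegration residual
#'
#' The 9-dim residual (rotation, velocity, position blocks) between a
#' preintegrated delta and a pair of keyframe states, with first-order bias
#' correction taken from `state_i`. Zero when the states are exactly
#' consistent with the bias-corrected delta and gravity.
#'
#' @param delta a [preintegrate()] result built over the interval (i, j).
#' @param state_i,state_j [imu_state()]s at the window ends.
#' @param noise a [noise_spec()].
#' @param whiten if `TRUE`, premultiply by the inverse Cholesky factor of the
#'   propagated delta covariance.
#' @return numeric length-9 residual.
#' @export
preint_residual <- function(delta, state_i, state_j, noise, whiten = FALSE) {
  cd <- .preint_corrected(delta, state_i$b)
  dT <- delta$dT
  g <- noise$g
  rR <- rot_log(t(cd$dR) %*% t(state_i$R) %*% state_j$R)
  rV <- as.numeric(t(state_i$R) %*% (state_j$v - state_i$v - g * dT)) - cd$dv
  rP <- as.numeric(t(state_i$R) %*%
    (state_j$p - state_i$p - state_i$v * dT - 0.5 * g * dT^2)) - cd$dp
  r <- c(rR, rV, rP)
  if (whiten) r <- as.numeric(delta$Linv %*% r)
  r
}

#' Bias random-walk residual
#'
#' Difference of consecutive keyframe biases, optionally whitened by the
#' random-walk covariance over the interval (std `sigma_bw * sqrt(dT)` per
#' component), so a fixed bias step whitens as `1/sqrt(dT)`.
#'
#' @param bias_i,bias_j length-6 biases (gyro, accel).
#' @param dT keyframe interval (s).
#' @param noise a [noise_spec()].
#' @param whiten whiten by the random-walk covariance.
#' @return numeric length-6 residual.
#' @export
bias_residual <- function(bias_i, bias_j, dT = 1, noise = noise_spec(),
                          whiten = FALSE) {
  r <- as.numeric(bias_j) - as.numeric(bias_i)
  if (whiten)
    r <- r / (c(rep(noise$sigma_bw_g, 3), rep(noise$sigma_bw_a, 3)) * sqrt(dT))
  r
}

#' Keyframe angular-velocity residual
#'
#' Ties the estimated instantaneous angular velocity to the raw gyro sample
#' coinciding with the keyframe: `omega_hat + b_gyro - omega_meas`.
#'
#' @param omega_hat estimated angular velocity (rad/s).
#' @param b_w gyro bias (rad/s).
#' @param omega_meas gyro measurement at the keyframe (rad/s).
#' @return numeric length-3 residual.
#' @export
angvel_residual <- function(omega_hat, b_w, omega_meas) {
  as.numeric(omega_hat) + as.numeric(b_w) - as.numeric(omega_meas)
}
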