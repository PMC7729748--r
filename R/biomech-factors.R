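# Biomechanical and anthropometric residual models. These R implementations
# are the reference definitions; the optimizer evaluates the same models in
# compiled code, and the two routes are cross-checked in the test suite.

#' Relative angular velocity across a joint
#'
#' Expressed in the proximal IMU frame A:
#' `m = t(R_A) %*% R_B %*% omega_B - omega_A`.
#'
#' @param R_A,R_B 3x3 orientations of the flanking IMUs (body-to-navigation).
#' @param omega_A,omega_B body-frame angular velocities (rad/s).
#' @return numeric length-3 (rad/s), in frame A.
#' @export
relative_angvel <- function(R_A, R_B, omega_A, omega_B) {
  as.numeric(t(R_A) %*% R_B %*% omega_B) - as.numeric(omega_A)
}

#' Knee pseudo-hinge residual
#'
#' For a point-rotation hinge the relative angular velocity across the joint
#' is parallel to the hinge axis, so its component orthogonal to the axis is
#' the model error: `e = m - (m . r) r`. The residual always lies in the
#' tangent plane of `r` and is invariant under `r -> -r` (the knee-axis sign
#' ambiguity; see [disambiguate_axes()]). Swapping the A/B arguments gives
#' the residual for the axis expressed in the distal IMU frame.
#'
#' @param r unit hinge axis in frame A.
#' @inheritParams relative_angvel
#' @return numeric length-3 residual (rad/s).
#' @export
hinge_residual <- function(r, R_A, R_B, omega_A, omega_B) {
  .check_unit(r)
  m <- relative_angvel(R_A, R_B, omega_A, omega_B)
  m - sum(m * r) * r
}

#' Constrained joint-center residual
#'
#' Two IMUs flanking a ball joint each carry a static vector to the common
#' rotation center; composed with the IMU poses these must name the same
#' navigation-frame point: `e = X_A(s_A) - X_B(s_B)`. The residual is
#' invariant to left-composition of both poses with a common rigid transform,
#' which is the gauge freedom anchored by [add_gauge_priors()].
#'
#' @param X_A,X_B [pose()]s of the flanking IMUs.
#' @param s_A,s_B static IMU-frame offsets to the joint center (m).
#' @return numeric length-3 residual (m).
#' @export
joint_center_residual <- function(X_A, s_A, X_B, s_B) {
  pose_act(X_A, s_A) - pose_act(X_B, s_B)
}

#' Knee-axis / segment-proximal angle residual
#'
#' The angle between the knee axis and the segment's proximal direction is
#' not orthogonal in general; its population distribution constrains where
#' along the medial/lateral line the knee center can lie. Residual:
#' `mu - acos(r . u)` with `u` the normalized proximal vector
#' `(s_prox - s_dist)`.
#'
#' @param r unit knee axis (IMU frame).
#' @param s_prox,s_dist IMU-frame offsets to the proximal and distal joint
#'   centers of the segment (m).
#' @param prior list with `mu` and `sigma` (rad).
#' @return scalar residual (rad).
#' @export
axis_segment_angle_residual <- function(r, s_prox, s_dist, prior) {
  .check_unit(r)
  w <- as.numeric(s_prox) - as.numeric(s_dist)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("zero-length segment: s_prox equals s_dist")
  cth <- sum(r * w) / nw
  if (abs(cth) > 1) {
    if (abs(cth) > 1 + 1e-9)
      message("axis_segment_angle_residual: clamped cos(angle) = ", cth)
    cth <- sign(cth)
  }
  prior$mu - acos(cth)
}

#' Anthropometric segment-length residual
#'
#' `||s_j1 - s_j2|| - mu_L`: the distance between the two joint centers
#' adjacent to one IMU, constrained by a population length prior.
#'
#' @param s_j1,s_j2 IMU-frame offsets to the two joint centers (m).
#' @param prior list with `mu` (m); `sigma` is used by the estimator for
#'   whitening.
#' @return scalar residual (m).
#' @export
segment_length_residual <- function(s_j1, s_j2, prior) {
  sqrt(sum((as.numeric(s_j1) - as.numeric(s_j2))^2)) - prior$mu
}

#' Hard min/max length window penalty
#'
#' Continuously differentiable one-sided penalty: zero on
#' `[lmin, lmax]`, `(x - lmax) * tanh(a (x - lmax))^2` above and the mirrored
#' form below. The sharpness `a` (1/m) tunes the strength of the constraint.
#'
#' @param x segment length (m), nonnegative.
#' @param prior list with `lmin`, `lmax`, `a`.
#' @return scalar penalty (m), always nonnegative.
#' @export
length_window_penalty <- function(x, prior) {
  stopifnot(x >= 0)
  if (x > prior$lmax) return((x - prior$lmax) * tanh(prior$a * (x - prior$lmax))^2)
  if (x < prior$lmin) return((prior$lmin - x) * tanh(prior$a * (prior$lmin - x))^2)
  0
}

#' Cross-leg segment-length discrepancy residual
#'
#' Difference between right and left segment lengths, e.g.
#' `||s_2rh - s_2rk|| - ||s_5lh - s_5lk||` for the femur. Population
#' discrepancy is zero-mean with a small std (0.8 cm femur, 0.6 cm tibia).
#'
#' @param s_r1,s_r2 right-leg IMU-frame joint-center offsets (m).
#' @param s_l1,s_l2 left-leg counterparts.
#' @return scalar residual (m); antisymmetric under swapping the legs.
#' @export
discrepancy_residual <- function(s_r1, s_r2, s_l1, s_l2) {
  sqrt(sum((as.numeric(s_r1) - as.numeric(s_r2))^2)) -
    sqrt(sum((as.numeric(s_l1) - as.numeric(s_l2))^2))
}

#' Composite two-population prior
#'
#' Combines male and female anthropometric distributions into the single
#' wider distribution `N((mu_M + mu_F)/2, sigma_M^2 + sigma_F^2)`.
#'
#' @param mu_M,sigma_M,mu_F,sigma_F per-population mean and std.
#' @return list with `mu` and `sigma`.
#' @export
compose_population_prior <- function(mu_M, sigma_M, mu_F, sigma_F) {
  stopifnot(sigma_M > 0, sigma_F > 0)
  list(mu = (mu_M + mu_F) / 2, sigma = sqrt(sigma_M^2 + sigma_F^2))
}

#' Fit a zero-mean Gaussian covariance to residual samples
#'
#' Maximum-likelihood covariance of a zero-mean Gaussian,
#' `1/N * sum(e e^T)`. All residual models in this package are zero-mean by
#' construction, so no mean is estimated. With fewer samples than needed for
#' full rank the estimate is regularized by a small diagonal jitter (with a
#' warning).
#'
#' @param samples N x d matrix of residual samples.
#' @return d x d symmetric positive semi-definite covariance.
#' @export
fit_noise_covariance <- function(samples) {
  samples <- rbind(samples)
  n <- nrow(samples); d <- ncol(samples)
  S <- crossprod(samples) / n
  S <- (S + t(S)) / 2
  if (n < d + 1 || qr(S)$rank < d) {
    warning("fit_noise_covariance: rank-deficient sample set; ",
            "adding diagonal jitter")
    S <- S + diag(d) * max(mean(diag(S)), 1e-12) * 1e-9
  }
  S
}

#' Subject-calibrated anthropometric priors
#'
#' When a subject's anthropometry has been measured precisely, the
#' population priors can be re-centered on the measured values (optionally
#' with tighter stds) to act as near-hard constraints. This helper builds
#' such a prior set from a synthetic [make_skeleton()] truth: segment-length
#' means are replaced by the subject's true lengths (left/right averaged,
#' matching the single prior shared by both legs) and axis-segment angle
#' means by the subject's true angles.
#'
#' @param skeleton a [make_skeleton()] result.
#' @param priors base priors to re-center.
#' @return priors list in the [default_anthro_priors()] layout.
#' @export
calibrated_priors <- function(skeleton, priors = default_anthro_priors()) {
  len <- priors$lengths
  len$mu[len$name == "femur"] <- mean(skeleton$femur)
  len$mu[len$name == "tibia"] <- mean(skeleton$tibia)
  len$mu[len$name == "femoral_head_separation"] <- skeleton$hip_width
  priors$lengths <- len
  axs <- priors$axis_segment
  th <- skeleton$axis_angles_deg
  axs$mu_deg[axs$segment == "femur" & axs$side == "right"] <- th$fr
  axs$mu_deg[axs$segment == "tibia" & axs$side == "right"] <- th$tr
  axs$mu_deg[axs$segment == "femur" & axs$side == "left"] <- th$fl
  axs$mu_deg[axs$segment == "tibia" & axs$side == "left"] <- th$tl
  priors$axis_segment <- axs
  priors
}

#' Packaged anthropometric and axis-alignment priors
#'
#' Reads the shipped prior tables: axis-segment angle distributions per
#' segment/side, segment-length distributions with hard windows (tibia,
#' femur, femoral head separation), cross-leg discrepancy stds, and the
#' default window sharpness.
#'
#' @param path optional path to an alternative YAML file.
#' @return list with data.frames `axis_segment`, `lengths`, `discrepancy`
#'   and scalar `window_sharpness`.
#' @export
default_anthro_priors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anthro_priors.yaml", package = "imumocap")
  y <- yaml::read_yaml(path)
  rb <- function(lst) do.call(rbind, lapply(lst, function(r) as.data.frame(r)))
  list(axis_segment = rb(y$axis_segment),
       lengths = rb(y$lengths),
       discrepancy = rb(y$discrepancy),
       window_sharpness = y$window_sharpness)
}
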