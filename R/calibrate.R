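# Component-level functional calibrators: recover the hinge axis and the
# joint-center offsets from given orientation / angular-velocity / pose
# trajectories by Gauss-Newton on the corresponding residual models alone.
# These are the building blocks the full smoother couples together; on their
# own they are useful for initialization, diagnostics and recovery studies.

#' Fit a knee hinge axis from orientation and angular-velocity trajectories
#'
#' Minimizes the summed squared hinge residual over the unit sphere: the
#' relative angular velocity across the joint, expressed in frame A, should
#' be parallel to the static axis. Initialized (by default) at the principal
#' eigenvector of the relative angular-velocity scatter, then refined by
#' Gauss-Newton in the 2-dim sphere tangent chart. The recovered axis is
#' defined up to sign.
#'
#' @param R_A,R_B 3 x 3 x N orientation trajectories of the proximal and
#'   distal IMU.
#' @param omega_A,omega_B 3 x N body-frame angular velocities (rad/s).
#' @param r0 optional initial unit axis.
#' @param max_iter,tol Gauss-Newton controls.
#' @return list with `axis` (unit 3-vector in frame A), `rmse` (rad/s) and
#'   `iterations`.
#' @export
fit_hinge_axis <- function(R_A, R_B, omega_A, omega_B, r0 = NULL,
                           max_iter = 50, tol = 1e-14) {
  m <- .rotarr_vec(.rotarr_tmul(R_A, R_B), omega_B) - omega_A
  if (is.null(r0)) {
    ev <- eigen(tcrossprod(m), symmetric = TRUE)
    r0 <- ev$vectors[, 1]
  }
  r <- r0 / sqrt(sum(r0^2))
  n <- ncol(m)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    B <- sphere_basis(r)
    cc <- colSums(m * r)
    e <- m - outer(r, cc)                 # residuals, 3 x N
    H <- matrix(0, 2, 2)
    gv <- numeric(2)
    for (k in seq_len(n)) {
      Jk <- -(tcrossprod(r, m[, k]) + cc[k] * diag(3)) %*% B
      H <- H + crossprod(Jk)
      gv <- gv + as.numeric(crossprod(Jk, e[, k]))
    }
    d <- solve(H + 1e-15 * diag(2), -gv)
    r <- sphere_retract(r, d)
    if (sum(d^2) < tol^2) break
  }
  cc <- colSums(m * r)
  e <- m - outer(r, cc)
  list(axis = r, rmse = sqrt(mean(colSums(e^2))), iterations = iters)
}

#' Fit joint-center offsets from two pose trajectories
#'
#' Solves the linear least-squares problem in the static offsets
#' `(s_A, s_B)` for the constrained joint-center model: over all frames,
#' `R_A s_A + p_A` and `R_B s_B + p_B` should name the same point. The
#' normal equations are formed in closed form. The problem is only
#' well-posed when both bodies rotate in multiple DOF about the joint (a
#' pure hinge leaves the component along the hinge axis free).
#'
#' @param R_A,R_B 3 x 3 x N orientation trajectories.
#' @param p_A,p_B 3 x N positions (m).
#' @return list with `s_A`, `s_B` (m) and `rmse` (m).
#' @export
fit_joint_offsets <- function(R_A, p_A, R_B, p_B) {
  n <- dim(R_A)[3]
  RtR <- .rotarr_tmul(R_A, R_B)            # t(R_A) R_B per frame
  d <- p_A - p_B
  H <- matrix(0, 6, 6)
  H[1:3, 1:3] <- n * diag(3)
  H[4:6, 4:6] <- n * diag(3)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) S[i, j] <- sum(RtR[i, j, ])
  H[1:3, 4:6] <- -S
  H[4:6, 1:3] <- -t(S)
  rhs <- c(-rowSums(.rotarr_tvec(R_A, d)), rowSums(.rotarr_tvec(R_B, d)))
  x <- solve(H + 1e-12 * diag(6), rhs)
  s_A <- x[1:3]; s_B <- x[4:6]
  e <- .rotarr_vec(R_A, s_A) + p_A - .rotarr_vec(R_B, s_B) - p_B
  list(s_A = s_A, s_B = s_B, rmse = sqrt(mean(colSums(e^2))))
}
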