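#' Rotation exponential map
#'
#' Maps a rotation vector (axis times angle, rad) to a proper rotation matrix
#' via the SO(3) exponential (Rodrigues formula). The zero vector maps to the
#' identity.
#'
#' @param omega numeric length-3 rotation vector (rad).
#' @return 3x3 rotation matrix.
#' @export
rot_exp <- function(omega) {
  stopifnot(is.numeric(omega), length(omega) == 3, all(is.finite(omega)))
  rot_exp_cpp(omega)
}

#' Rotation logarithm map
#'
#' Inverse of [rot_exp()]. Returns the rotation vector with angle in
#' \eqn{[0, \pi]}; rotations near \eqn{\pi} are handled by a numerically
#' stable branch (axis extracted from the dominant diagonal of
#' \eqn{(R + I)/2}), so the result is never NaN. At exactly \eqn{\pi} the
#' axis sign is canonical (first nonzero component positive).
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector (rad).
#' @export
rot_log <- function(R) {
  .check_rotation(R)
  as.numeric(rot_log_cpp(R))
}

.check_rotation <- function(R, tol = 1e-6) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), all(is.finite(R)))
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("not a valid rotation matrix")
  invisible(R)
}

#' Rigid transform (pose)
#'
#' A pose holds an orientation `R` (mapping body-frame vectors into the
#' navigation frame) and a position `p` (m). Acting on a point computes
#' `R %*% x + p`.
#'
#' @param R 3x3 rotation matrix.
#' @param p numeric length-3 translation (m).
#' @return object of class `"pose"`.
#' @export
pose <- function(R = diag(3), p = c(0, 0, 0)) {
  .check_rotation(R)
  stopifnot(length(p) == 3, all(is.finite(p)))
  structure(list(R = R, p = as.numeric(p)), class = "pose")
}

#' Apply a pose to a point
#' @param X a [pose()].
#' @param x numeric length-3 point (m), expressed in the pose's body frame.
#' @return numeric length-3 point in the navigation frame.
#' @export
pose_act <- function(X, x) {
  stopifnot(inherits(X, "pose"), length(x) == 3)
  as.numeric(X$R %*% x + X$p)
}

#' @rdname pose
#' @param X,Y poses to compose (`X` then `Y` applied in `X`'s frame).
#' @export
pose_compose <- function(X, Y) {
  pose(X$R %*% Y$R, as.numeric(X$R %*% Y$p + X$p))
}

#' @rdname pose
#' @export
pose_inverse <- function(X) {
  pose(t(X$R), as.numeric(-t(X$R) %*% X$p))
}

#' Deterministic tangent basis on the unit sphere
#'
#' Returns a 3x2 orthonormal basis of the tangent plane at `r`, constructed
#' by crossing `r` with the canonical axis that follows its largest-magnitude
#' component. The rule is deterministic so retractions are reproducible.
#'
#' @param r unit 3-vector.
#' @return 3x2 matrix with orthonormal columns, both orthogonal to `r`.
#' @export
sphere_basis <- function(r) {
  .check_unit(r)
  sphere_basis_cpp(r)
}

.check_unit <- function(r, tol = 1e-6) {
  stopifnot(is.numeric(r), length(r) == 3, all(is.finite(r)))
  if (abs(sqrt(sum(r^2)) - 1) > tol) stop("axis is not unit norm")
  invisible(r)
}

#' Retract a tangent step on the unit sphere
#'
#' Geodesic retraction: `delta` (2-vector in the [sphere_basis()] chart) is
#' mapped along the great circle, so the result is exactly unit norm and the
#' step length equals the great-circle distance.
#'
#' @param r unit 3-vector.
#' @param delta numeric length-2 tangent coordinates.
#' @return unit 3-vector.
#' @export
sphere_retract <- function(r, delta) {
  .check_unit(r)
  stopifnot(length(delta) == 2, all(is.finite(delta)))
  as.numeric(sphere_retract_cpp(r, delta))
}

#' Local coordinates between two manifold elements
#'
#' Inverse of the respective retraction: `manifold_local(a, b)` returns the
#' tangent vector `v` at `a` with `retract(a, v) = b`. Dispatches on the type
#' of `a`: a 3x3 matrix is treated as a rotation (tangent = rotation vector,
#' retraction `a %*% rot_exp(v)`), a [pose()] as a rigid transform (rotation
#' coordinates first, then translation), and a unit 3-vector as a sphere
#' point (coordinates in the [sphere_basis()] chart). An antipodal unit-axis
#' pair has no unique tangent and is signalled as an error.
#'
#' @param a,b two elements of the same manifold.
#' @return numeric tangent vector (length 3, 6 or 2).
#' @export
manifold_local <- function(a, b) {
  if (inherits(a, "pose")) {
    stopifnot(inherits(b, "pose"))
    return(c(rot_log(t(a$R) %*% b$R), b$p - a$p))
  }
  if (is.matrix(a)) {
    .check_rotation(a); .check_rotation(b)
    return(rot_log(t(a) %*% b))
  }
  .check_unit(a); .check_unit(b)
  cth <- sum(a * b)
  if (cth < -1 + 1e-9)
    stop("antipodal unit axes: tangent direction is ambiguous")
  th <- acos(min(1, max(-1, cth)))
  if (th < 1e-14) return(c(0, 0))
  dir <- b - cth * a
  dir <- dir / sqrt(sum(dir^2))
  as.numeric(crossprod(sphere_basis(a), th * dir))
}

# Project a nearly orthonormal matrix back onto SO(3).
project_rotation <- function(R) orthonormalize_cpp(R)
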