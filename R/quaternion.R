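# Quaternion algebra and attitude kinematics.
#
# Conventions (used consistently package-wide):
#   * scalar-first unit quaternions q = (q0, q1, q2, q3), Hamilton product;
#   * q maps the sensor (body) frame to the global frame: a vector v expressed
#     in sensor axes appears in global axes as R(q) %*% v;
#   * global frame is right-handed with z up, so the specific force measured
#     by a resting accelerometer points along +z in the global frame.

#' Construct a quaternion
#'
#' @param q0 scalar part.
#' @param q1,q2,q3 vector part.
#' @param normalize normalize to unit length (default `TRUE`).
#' @return numeric length-4 vector `c(q0, q1, q2, q3)`.
#' @examples
#' quaternion(1, 0, 0, 0)
#' @export
quaternion <- function(q0, q1, q2, q3, normalize = TRUE) {
  q <- c(q0, q1, q2, q3)
  if (length(q) != 4L || !all(is.finite(q)))
    stopf("quaternion components must be four finite numbers")
  if (normalize) q <- quat_normalize(q)
  q
}

#' Identity quaternion
#' @return the identity rotation `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Normalize a quaternion to unit length
#' @param q quaternion.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (!is.finite(n) || n < .Machine$double.eps)
    stopf("cannot normalize a zero-norm quaternion")
  q / n
}

#' Hamilton product of two quaternions
#' @param p,q quaternions (scalar first).
#' @return the product `p * q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q quaternion.
#' @return conjugate quaternion.
#' @export
quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

#' Quaternion from an axis-angle rotation
#' @param axis rotation axis (3-vector, need not be unit).
#' @param angle rotation angle (rad).
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- norm3(axis)
  if (n < .Machine$double.eps) stopf("rotation axis must be non-zero")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Rotation matrix of a quaternion (sensor-to-global)
#' @param q unit quaternion.
#' @return 3 x 3 rotation matrix `R` with `v_global = R %*% v_sensor`.
#' @export
quat_to_matrix <- function(q) {
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  matrix(c(
    1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)),
    nrow = 3L, byrow = TRUE)
}

#' Propagate a quaternion through one gyroscope sample
#'
#' Integrates the quaternion kinematic differential equation
#' \eqn{\dot q = \tfrac12 \Omega(\omega) q} by a first-order step followed by
#' renormalization.  \eqn{\omega} is the body-frame angular rate; the skew
#' matrix form is equivalent to the Hamilton product \eqn{\tfrac12 q \otimes
#' (0, \omega)}.
#'
#' @param q unit quaternion (sensor to global).
#' @param omega body angular rate, rad/s (3-vector).
#' @param dt time step in seconds (> 0).
#' @return unit quaternion advanced by `dt`.
#' @examples
#' quat_propagate(quat_identity(), c(0, 0, pi / 2), 0.01)
#' @export
quat_propagate <- function(q, omega, dt) {
  if (!is_number(dt) || dt <= 0) stopf("dt must be a positive finite number")
  if (length(omega) != 3L || !all(is.finite(omega)))
    stopf("omega must be a finite 3-vector")
  dq <- 0.5 * quat_multiply(q, c(0, omega))
  quat_normalize(q + dt * dq)
}

#' Euler angles (roll, pitch, yaw) of a quaternion
#'
#' Aerospace Z-Y-X sequence applied to the sensor-to-global rotation:
#' roll \eqn{\phi = \mathrm{atan2}(2(q_2 q_3 + q_0 q_1),\; q_0^2 - q_1^2 -
#' q_2^2 + q_3^2)}, pitch \eqn{\theta = \arcsin(-2(q_1 q_3 - q_0 q_2))}, yaw
#' \eqn{\psi = \mathrm{atan2}(2(q_1 q_2 + q_0 q_3),\; q_0^2 + q_1^2 - q_2^2 -
#' q_3^2)}.  The arcsine argument is clamped to \eqn{[-1, 1]} so pitch is
#' well-defined at the \eqn{\pm 90^\circ} singularity up to round-off.
#'
#' @param q unit quaternion.
#' @return list with elements `phi`, `theta`, `psi` (rad); `theta` in
#'   `[-pi/2, pi/2]`.
#' @export
quat_to_euler <- function(q) {
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  list(
    phi   = atan2(2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    theta = asin(clamp(-2 * (q1 * q3 - q0 * q2), -1, 1)),
    psi   = atan2(2 * (q1 * q2 + q0 * q3), q0^2 + q1^2 - q2^2 - q3^2))
}

#' Quaternion from Euler angles (roll, pitch, yaw)
#' @param phi,theta,psi roll, pitch, yaw (rad), Z-Y-X sequence.
#' @return unit quaternion.
#' @export
euler_to_quat <- function(phi, theta, psi) {
  quat_multiply(
    quat_multiply(quat_from_axis_angle(c(0, 0, 1), psi),
                  quat_from_axis_angle(c(0, 1, 0), theta)),
    quat_from_axis_angle(c(1, 0, 0), phi))
}

#' Spherical linear interpolation between quaternions
#'
#' Constant-angular-rate interpolation
#' \eqn{\mathrm{slerp}(q_m, q_n, t) = \frac{\sin((1-t)\theta)}{\sin\theta} q_m
#' + \frac{\sin(t\theta)}{\sin\theta} q_n}.  The sign of `qn` is flipped when
#' the quaternion dot product is negative (shortest-path), and the routine
#' falls back to [quat_nlerp()] when the arc is below 1e-6 rad, where
#' \eqn{\sin\theta} underflows.
#'
#' @param qm,qn unit quaternions.
#' @param t interpolation fraction in `[0, 1]`.
#' @return unit quaternion.
#' @export
quat_slerp <- function(qm, qn, t) {
  if (!is_number(t) || t < 0 || t > 1) stopf("t must lie in [0, 1]")
  d <- sum(qm * qn)
  if (d < 0) { qn <- -qn; d <- -d }
  d <- min(d, 1)
  theta <- acos(d)
  if (theta < 1e-6) return(quat_nlerp(qm, qn, t))
  s <- sin(theta)
  quat_normalize((sin((1 - t) * theta) / s) * qm + (sin(t * theta) / s) * qn)
}

#' Normalized linear interpolation between quaternions
#'
#' Linear blend renormalized to unit length; the small-angle limit of
#' [quat_slerp()] and its numerical fallback.
#'
#' @inheritParams quat_slerp
#' @return unit quaternion.
#' @export
quat_nlerp <- function(qm, qn, t) {
  if (!is_number(t) || t < 0 || t > 1) stopf("t must lie in [0, 1]")
  q <- qm + (qn - qm) * t
  n <- sqrt(sum(q * q))
  if (n < 1e-12)
    stopf("degenerate interpolation: antipodal quaternions at t = %g", t)
  q / n
}

#' Rotate a vector from the sensor frame into the global frame
#'
#' @param q unit quaternion (sensor to global).
#' @param v 3-vector in sensor axes.
#' @return 3-vector in global axes; use `quat_conjugate(q)` for the inverse
#'   transformation.
#' @export
rotate_vector <- function(q, v) {
  if (length(v) != 3L || !all(is.finite(v))) stopf("v must be a finite 3-vector")
  drop(quat_to_matrix(q) %*% v)
}
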