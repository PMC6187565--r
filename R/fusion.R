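# Attitude estimation: PI-feedback complementary filter.
#
# High-frequency attitude comes from gyroscope integration; low-frequency
# drift is removed by steering the integrated rates toward two reference
# directions, gravity (accelerometer) and the geomagnetic field
# (magnetometer), through a proportional-integral feedback on the
# cross-product error vectors.

#' Complementary-filter configuration
#'
#' @param kp proportional gain on the reference-vector error (dimensionless;
#'   the error vector is built from unit vectors so its magnitude is bounded
#'   by 1 and the gain absorbs the rad/s conversion).
#' @param ki integral gain (1/s); removes steady-state error from constant
#'   gyro bias.  The default makes the integral learn a residual bias
#'   within a few seconds — with a sluggish integral the heading error from
#'   even a well-estimated bias persists for most of a one-minute walk and
#'   dominates the position budget.
#' @param tau integration step for the integral accumulator (s); defaults to
#'   the sampling interval when `NULL`.
#' @param use_mag fuse magnetometer heading corrections when the sequence
#'   carries magnetometer data.
#' @param accel_gate relative tolerance on `| ||a|| - g | / g` beyond which
#'   the gravity correction is skipped (strong linear acceleration, e.g.
#'   swing phase); set `Inf` to disable gating.
#' @param gyro_gate angular-rate magnitude (rad/s) above which the gravity
#'   correction is skipped.  The accelerometer only measures gravity in the
#'   quasi-static state; mid-swing the specific-force norm can cross `g`
#'   with a badly wrong direction while the foot rotates fast, so the rate
#'   gate rejects exactly those samples.  Set `Inf` to disable.
#' @param mag_weight weight of the magnetic error relative to the gravity
#'   error inside the PI feedback.  A heading error only produces an error
#'   vector attenuated by the squared horizontal fraction of the field
#'   (about 0.23 for a 61-degree dip), so heading needs a stiffer loop than
#'   inclination to converge on the same time scale; the default restores
#'   comparable authority.
#' @param mag_static_only when a static mask is supplied to
#'   [fuse_sequence()], restrict the magnetic correction to static samples
#'   as well.  The field itself is motion-independent, but the heading error
#'   extracted from it couples to tilt errors, which are only guaranteed
#'   small while the gravity correction is active; correcting heading in the
#'   same quasi-static windows avoids chasing that coupling.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(kp = 2.0, ki = 2.0, tau = NULL, use_mag = TRUE,
                          accel_gate = 0.1, gyro_gate = 0.3, mag_weight = 10,
                          mag_static_only = TRUE) {
  if (!is_number(kp) || kp < 0 || !is_number(ki) || ki < 0)
    stopf("gains kp, ki must be non-negative")
  if (!is.null(tau) && (!is_number(tau) || tau <= 0))
    stopf("tau must be positive")
  if (!is_number(mag_weight) || mag_weight < 0)
    stopf("mag_weight must be non-negative")
  structure(list(kp = kp, ki = ki, tau = tau, use_mag = isTRUE(use_mag),
                 accel_gate = accel_gate, gyro_gate = gyro_gate,
                 mag_weight = mag_weight,
                 mag_static_only = isTRUE(mag_static_only)),
            class = "fusion_config")
}

#' Gravity reference error vector
#'
#' Cross product of the normalized measured acceleration with the predicted
#' sensor-frame gravity direction `c = R(q)' [0,0,1]'`.  Zero when the
#' estimated attitude explains the measured gravity direction; for unit
#' inputs its magnitude is the sine of the angle between them.
#'
#' @param a_meas measured acceleration (3-vector, any magnitude > 0).
#' @param q current attitude estimate (unit quaternion, sensor to global).
#' @return 3-vector error in the sensor frame.
#' @export
gravity_error <- function(a_meas, q) {
  n <- norm3(a_meas)
  if (!is.finite(n) || n <= 0) stopf("zero-norm acceleration measurement")
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  cpred <- c(2 * (q1 * q3 - q0 * q2),
             2 * (q2 * q3 + q0 * q1),
             q0^2 - q1^2 - q2^2 + q3^2)
  cross3(a_meas / n, cpred)
}

#' Magnetic reference error vector (heading-only)
#'
#' The measured field is rotated to the global frame and projected onto the
#' reference form `(sqrt(bx^2 + by^2), 0, bz)` — i.e. the reference keeps the
#' measured dip angle and pins the horizontal component to the global x axis.
#' The raw error is the cross product of the normalized measurement with the
#' predicted sensor-frame reference; because the field is dipped, that cross
#' product carries tilt components, so it is projected onto the predicted
#' sensor-frame gravity axis before use.  The result is a pure heading
#' correction: it can never alter the estimated gravity direction.
#'
#' @param m_meas calibrated magnetometer measurement (3-vector).
#' @param q current attitude estimate (unit quaternion).
#' @return 3-vector error in the sensor frame, parallel to the predicted
#'   gravity axis; zero (with a warning) when the field is vertical within
#'   1e-6, where heading is unobservable.
#' @export
magnetic_error <- function(m_meas, q) {
  n <- norm3(m_meas)
  if (!is.finite(n) || n <= 0) stopf("zero-norm magnetometer measurement")
  mhat <- m_meas / n
  R <- quat_to_matrix(q)
  h <- drop(R %*% mhat)
  hh <- sqrt(h[1L]^2 + h[2L]^2)
  if (hh < 1e-6) {
    warnf("vertical magnetic field: heading unobservable, no correction")
    return(c(0, 0, 0))
  }
  b <- c(hh, 0, h[3L])
  b <- b / norm3(b)
  cpred <- drop(crossprod(R, b))
  e <- cross3(mhat, cpred)
  gpred <- R[3L, ]          # predicted sensor-frame gravity direction
  sum(e * gpred) * gpred
}

#' Proportional-integral correction of angular rates
#'
#' Implements the feedback `omega_corrected = omega + kp * err +
#' ki * integral`, with the integral accumulator advanced by `err * tau`
#' before use.
#'
#' @param omega measured angular rate (rad/s, 3-vector).
#' @param err reference error vector (from [gravity_error()] /
#'   [magnetic_error()], possibly summed).
#' @param state list with accumulator `integral` (3-vector); use
#'   `fusion_state()` for a fresh one.
#' @param cfg a [fusion_config()]; `cfg$tau` must be set.
#' @return list with `omega` (corrected rate) and `state` (updated).
#' @export
pi_correct <- function(omega, err, state, cfg) {
  tau <- cfg$tau
  if (is.null(tau)) stopf("cfg$tau must be set for pi_correct")
  integral <- state$integral + err * tau
  list(omega = omega + cfg$kp * err + cfg$ki * integral,
       state = list(integral = integral))
}

#' Fresh fusion state
#' @return list with a zero integral accumulator.
#' @export
fusion_state <- function() list(integral = c(0, 0, 0))

#' Initial attitude from a static capture
#'
#' Roll and pitch from the mean accelerometer direction over the first
#' `n_static` samples; yaw from the tilt-compensated mean magnetometer when
#' available and requested, else 0.
#'
#' @param seq an [imu_sequence()] starting with quiet standing.
#' @param n_static number of samples to average (default: one second).
#' @param use_mag derive yaw from the magnetometer.
#' @return unit quaternion.
#' @export
initial_attitude <- function(seq, n_static = NULL, use_mag = TRUE) {
  n <- nrow(seq$acc)
  if (is.null(n_static)) n_static <- min(n, round(seq$fs))
  a <- colMeans(seq$acc[seq_len(n_static), , drop = FALSE])
  phi <- atan2(a[2L], a[3L])
  theta <- atan2(-a[1L], sqrt(a[2L]^2 + a[3L]^2))
  psi <- 0
  if (use_mag && !is.null(seq$mag)) {
    m <- colMeans(seq$mag[seq_len(n_static), , drop = FALSE])
    mh <- rotate_vector(euler_to_quat(phi, theta, 0), m)
    if (sqrt(mh[1L]^2 + mh[2L]^2) > 1e-9) psi <- atan2(-mh[2L], mh[1L])
  }
  euler_to_quat(phi, theta, psi)
}

#' Fuse an IMU sequence into an attitude trajectory
#'
#' Per sample: compute the gravity error (gated out when the specific-force
#' magnitude deviates from gravity by more than `accel_gate`, i.e. under
#' strong linear acceleration) and, optionally, the magnetic heading error;
#' apply the PI correction to the measured rates; propagate the quaternion by
#' [quat_propagate()].  With `kp = ki = 0` this reduces exactly to open-loop
#' gyro integration.
#'
#' @param seq an [imu_sequence()] with calibrated channels.
#' @param cfg a [fusion_config()].
#' @param q0 initial attitude (unit quaternion); from [initial_attitude()]
#'   when `NULL`.
#' @param g gravity magnitude (m/s^2).
#' @param static_mask optional per-sample logical (or 0/1) vector marking
#'   quasi-static samples (e.g. a detected stance mask); when supplied, the
#'   gravity correction is additionally restricted to these samples.  The
#'   amplitude gates alone cannot reject mid-swing samples whose
#'   specific-force norm happens to cross `g` while its direction is far
#'   from vertical; magnetic corrections remain active throughout since the
#'   field is motion-independent.
#' @return n x 4 matrix of unit quaternions, one row per sample (row 1 is
#'   `q0`).
#' @export
fuse_sequence <- function(seq, cfg = fusion_config(), q0 = NULL,
                          g = STANDARD_GRAVITY, static_mask = NULL) {
  stopifnot(inherits(seq, "imu_sequence"))
  t <- seq$t
  dt <- diff(t)
  gaps <- which(dt > 5 / seq$fs)
  if (length(gaps))
    stopf("timestamp gap(s) exceeding 5 sample periods at index(es) %s",
          paste(utils::head(gaps, 5L), collapse = ", "))
  if (is.null(q0)) q0 <- initial_attitude(seq, use_mag = cfg$use_mag)
  n <- length(t)
  if (!is.null(static_mask)) {
    if (length(static_mask) != n)
      stopf("static_mask length must match the sequence")
    static_mask <- as.logical(static_mask)
  }
  acc <- seq$acc
  gyro <- seq$gyro
  mag <- if (cfg$use_mag) seq$mag else NULL
  out <- matrix(NA_real_, n, 4L)
  out[1L, ] <- q <- quat_normalize(q0)
  integral <- c(0, 0, 0)
  kp <- cfg$kp; ki <- cfg$ki
  closed_loop <- (kp > 0 || ki > 0)
  for (i in 2L:n) {
    h <- dt[i - 1L]
    tau <- if (is.null(cfg$tau)) h else cfg$tau
    # midpoint rate over the step: second-order accurate where the
    # right-endpoint rate leaves an O(dt^2 * omega-dot) phase lag that is
    # systematic over every swing
    w <- 0.5 * (gyro[i - 1L, ] + gyro[i, ])
    if (closed_loop) {
      err <- c(0, 0, 0)
      a <- acc[i, ]
      an <- sqrt(sum(a * a))
      wn <- sqrt(sum(gyro[i, ]^2))
      if (an > 0 && abs(an - g) / g <= cfg$accel_gate &&
          wn <= cfg$gyro_gate &&
          (is.null(static_mask) || static_mask[i])) {
        q0s <- q[1L]; q1s <- q[2L]; q2s <- q[3L]; q3s <- q[4L]
        cpred <- c(2 * (q1s * q3s - q0s * q2s),
                   2 * (q2s * q3s + q0s * q1s),
                   q0s^2 - q1s^2 - q2s^2 + q3s^2)
        ah <- a / an
        err <- err + c(ah[2L] * cpred[3L] - ah[3L] * cpred[2L],
                       ah[3L] * cpred[1L] - ah[1L] * cpred[3L],
                       ah[1L] * cpred[2L] - ah[2L] * cpred[1L])
      }
      if (!is.null(mag) &&
          !(cfg$mag_static_only && !is.null(static_mask) && !static_mask[i])) {
        m <- mag[i, ]
        mn <- sqrt(sum(m * m))
        if (mn > 0) {
          R <- quat_to_matrix(q)
          mh <- m / mn
          hvec <- drop(R %*% mh)
          hh <- sqrt(hvec[1L]^2 + hvec[2L]^2)
          if (hh >= 1e-6) {
            b <- c(hh, 0, hvec[3L])
            b <- b / sqrt(sum(b * b))
            cpm <- drop(crossprod(R, b))
            em <- c(mh[2L] * cpm[3L] - mh[3L] * cpm[2L],
                    mh[3L] * cpm[1L] - mh[1L] * cpm[3L],
                    mh[1L] * cpm[2L] - mh[2L] * cpm[1L])
            gpred <- R[3L, ]  # heading-only: project onto gravity axis
            err <- err + cfg$mag_weight * sum(em * gpred) * gpred
          }
        }
      }
      integral <- integral + err * tau
      w <- w + kp * err + ki * integral
    }
    dq <- 0.5 * quat_multiply(q, c(0, w))
    q <- q + h * dq
    q <- q / sqrt(sum(q * q))
    out[i, ] <- q
  }
  out
}
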