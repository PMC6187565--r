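# Parametric lower-limb gait simulator.
#
# Produces ground-truth kinematics (poses, linear accelerations, body rates,
# stance masks, per-stride parameters) for foot/shank/thigh sensors on both
# sides, plus raw IMU/magnetometer streams through a configurable sensor
# error model.  Every configured gait parameter (stride length, clearance,
# cycle, stance fraction, knee profile) is realized exactly by construction,
# so the truth tables serve as oracles for the analysis pipeline.
#
# Trajectory primitives (stride phase tau in [0,1), stance for tau < s,
# swing sigma = (tau - s)/(1 - s)):
#   * foot advance: minimal-jerk septic smoothstep x = L s7(sigma) — zero
#     velocity, acceleration and jerk at both contacts;
#   * foot lift: z = h sin^4(pi sigma) — C^3, peak h at mid-swing;
#   * foot pitch / knee flexion / thigh swing: sine-based bumps, C^1 with
#     zero rate at the phase boundaries.
# Sagittal-plane convention: segment inclination theta is measured from the
# vertical, positive toward the sensor +x axis; the sensor-to-global
# rotation is about the y axis, so a static sensor reads
# (g sin theta, 0, g cos theta).

#' Gait model configuration
#'
#' Defaults follow healthy-adult walking scales: stride length 1.21 m, cycle
#' 1.32 s, clearance 0.22 m, stance fraction 0.65, knee flexion from 7.2 deg
#' (stance) to a 66.2 deg swing peak (range of motion 59 deg).
#'
#' @param n_strides strides per foot.
#' @param cycle_s stride (gait-cycle) duration, s.
#' @param stance_fraction fraction of the cycle in stance, in (0, 1).
#' @param stride_length_m distance between consecutive footprints of the
#'   same foot, m.
#' @param clearance_m peak swing foot elevation, m.
#' @param knee_peak_deg peak swing knee flexion, deg.
#' @param knee_min_deg stance knee flexion, deg.
#' @param thigh_amp_deg thigh swing amplitude about its mean inclination, deg.
#' @param foot_pitch_amp_deg swing foot-pitch amplitude, deg.
#' @param asymmetry optional per-side scaling, a list with any of `length`,
#'   `clearance`, `rom`, each `c(left, right)` multipliers (default 1).
#' @param fs sampling rate, Hz.
#' @param t_static initial quiet-standing duration, s (used downstream for
#'   bias/attitude initialization).
#' @param t_end terminal quiet-standing duration, s.
#' @param mag_field global geomagnetic reference field (arbitrary units),
#'   with a realistic downward dip by default.
#' @param seed simulator seed (used by the sensor error model).
#' @return object of class `gait_config`.
#' @export
gait_config <- function(n_strides = 10L, cycle_s = 1.32,
                        stance_fraction = 0.65, stride_length_m = 1.21,
                        clearance_m = 0.22, knee_peak_deg = 66.2,
                        knee_min_deg = 7.2, thigh_amp_deg = 15,
                        foot_pitch_amp_deg = 15, asymmetry = list(),
                        fs = 100, t_static = 2, t_end = 1,
                        mag_field = c(22, 0, -40), seed = 42L) {
  if (n_strides < 1L) stopf("n_strides must be >= 1")
  if (!is_number(cycle_s) || cycle_s <= 0) stopf("cycle_s must be > 0")
  if (!is_number(stance_fraction) || stance_fraction <= 0 ||
      stance_fraction >= 1)
    stopf("stance_fraction must lie in (0, 1)")
  if (stride_length_m <= 0 || clearance_m <= 0)
    stopf("stride length and clearance must be > 0")
  if (clearance_m > 0.9) stopf("clearance_m exceeds leg length: invalid config")
  if (knee_peak_deg <= knee_min_deg)
    stopf("knee_peak_deg must exceed knee_min_deg")
  asym <- list(length = c(1, 1), clearance = c(1, 1), rom = c(1, 1))
  for (nm in names(asymmetry)) {
    if (!nm %in% names(asym))
      stopf("unknown asymmetry component '%s'", nm)
    v <- asymmetry[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0))
      stopf("asymmetry$%s must be two positive scale factors (left, right)", nm)
    asym[[nm]] <- v
  }
  structure(list(n_strides = as.integer(n_strides), cycle_s = cycle_s,
                 stance_fraction = stance_fraction,
                 stride_length_m = stride_length_m, clearance_m = clearance_m,
                 knee_peak_deg = knee_peak_deg, knee_min_deg = knee_min_deg,
                 thigh_amp_deg = thigh_amp_deg,
                 foot_pitch_amp_deg = foot_pitch_amp_deg,
                 asymmetry = asym, fs = fs, t_static = t_static,
                 t_end = t_end, mag_field = mag_field, seed = as.integer(seed)),
            class = "gait_config")
}

#' Sensor error model
#'
#' Noise scales follow typical MEMS sensor grade (bias stability, 1-sigma):
#' accelerometer 0.02 m/s^2, gyroscope 1 deg/s, magnetometer 0.1 field
#' units.  Per-axis constant gyro biases are drawn once per sensor from
#' a zero-mean normal with SD `gyro_bias`.
#'
#' @param accel_noise_sd accelerometer white-noise SD, m/s^2.
#' @param gyro_noise_sd gyroscope white-noise SD, rad/s.
#' @param gyro_bias 1-sigma of the constant per-axis gyro bias, rad/s.
#' @param mag_noise_sd magnetometer white-noise SD, field units.
#' @param nonortho accelerometer misalignment, a [nonortho_angles()].
#' @param hard_iron additive magnetometer offset (3-vector, field units).
#' @param soft_iron multiplicative magnetometer distortion (3 x 3).
#' @param seed RNG seed for all sensor randomness.
#' @return object of class `sensor_error_model`.
#' @export
sensor_error_model <- function(accel_noise_sd = 0.02,
                               gyro_noise_sd = deg2rad(1),
                               gyro_bias = deg2rad(1),
                               mag_noise_sd = 0.1,
                               nonortho = nonortho_angles(deg2rad(0.5),
                                                          deg2rad(0.3),
                                                          deg2rad(0.8)),
                               hard_iron = c(10, -5, 3),
                               soft_iron = diag(c(1.1, 0.9, 1.0)),
                               seed = 42L) {
  if (accel_noise_sd < 0 || gyro_noise_sd < 0 || gyro_bias < 0 ||
      mag_noise_sd < 0)
    stopf("noise SDs must be >= 0")
  structure(list(accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
                 mag_noise_sd = mag_noise_sd, nonortho = nonortho,
                 hard_iron = hard_iron, soft_iron = soft_iron,
                 seed = as.integer(seed)),
            class = "sensor_error_model")
}

#' Ideal (error-free) sensor model
#' @param seed RNG seed (unused when all noise is zero, kept for symmetry).
#' @return a [sensor_error_model()] with zero noise and identity distortions.
#' @export
ideal_sensor_model <- function(seed = 42L) {
  sensor_error_model(accel_noise_sd = 0, gyro_noise_sd = 0, gyro_bias = 0,
                     mag_noise_sd = 0, nonortho = nonortho_angles(0, 0, 0),
                     hard_iron = c(0, 0, 0), soft_iron = diag(3),
                     seed = seed)
}

# ---- trajectory primitives ------------------------------------------------
# All swing primitives are C^3 at the stance boundaries (zero velocity,
# acceleration and jerk), so sampled trapezoidal integration of the
# resulting accelerations converges at second order with no kink artifacts.

# minimal-jerk septic advance on [0,1]: value, d/dsigma, d2/dsigma2
.advance <- function(sg) {
  list(v = 35 * sg^4 - 84 * sg^5 + 70 * sg^6 - 20 * sg^7,
       d1 = 140 * sg^3 * (1 - sg)^3,
       d2 = 420 * sg^2 * (1 - sg)^2 * (1 - 2 * sg))
}

# sin^4 lift bump on [0,1]
.lift_bump <- function(sg) {
  s <- sin(pi * sg); cs <- cos(pi * sg)
  list(v = s^4,
       d1 = 4 * pi * s^3 * cs,
       d2 = 4 * pi^2 * s^2 * (3 * cs^2 - s^2))
}

# signed pitch bump sin(2 pi s) sin^2(pi s) on [0,1]
.pitch_bump <- function(sg) {
  list(v = sin(2 * pi * sg) * sin(pi * sg)^2,
       d1 = 2 * pi * cos(2 * pi * sg) * sin(pi * sg)^2 +
         pi * sin(2 * pi * sg)^2)
}

# knee flexion uses the same sin^4 bump as the foot lift: its angular
# acceleration vanishes at the swing boundaries, so the shank sensor's
# linear acceleration stays continuous across contacts
.flex_bump <- .lift_bump

# quintic smoothstep and derivatives (C^2 envelope ramp)
.h5 <- function(x) {
  list(v = 6 * x^5 - 15 * x^4 + 10 * x^3,
       d1 = 30 * x^4 - 60 * x^3 + 30 * x^2,
       d2 = 120 * x^3 - 180 * x^2 + 60 * x)
}

# Per-side foot/segment-angle kinematics over a time vector.
.side_kinematics <- function(t, cfg, side) {
  i <- if (side == "L") 1L else 2L
  Tc <- cfg$cycle_s
  s <- cfg$stance_fraction
  n <- cfg$n_strides
  L <- cfg$stride_length_m * cfg$asymmetry$length[i]
  h <- cfg$clearance_m * cfg$asymmetry$clearance[i]
  rom <- (cfg$knee_peak_deg - cfg$knee_min_deg) * cfg$asymmetry$rom[i]
  knee_min <- deg2rad(cfg$knee_min_deg)
  knee_rng <- deg2rad(rom)
  Af <- deg2rad(cfg$foot_pitch_amp_deg)
  At <- deg2rad(cfg$thigh_amp_deg)
  t0 <- cfg$t_static + if (side == "L") 0 else 0.5 * Tc

  u <- clamp((t - t0) / Tc, 0, n)
  k <- floor(u)
  tau <- u - k
  active <- (t >= t0) & (u < n)
  swing <- active & (tau >= s)
  sg <- ifelse(swing, (tau - s) / (1 - s), 0)
  sgdot <- 1 / ((1 - s) * Tc)

  cy <- .advance(sg); lb <- .lift_bump(sg); pb <- .pitch_bump(sg)
  fb <- .flex_bump(sg)
  sw <- as.numeric(swing)

  x <- k * L + sw * L * cy$v
  dx <- sw * L * cy$d1 * sgdot
  ddx <- sw * L * cy$d2 * sgdot^2
  z <- sw * h * lb$v
  dz <- sw * h * lb$d1 * sgdot
  ddz <- sw * h * lb$d2 * sgdot^2
  th_f <- sw * Af * pb$v
  dth_f <- sw * Af * pb$d1 * sgdot

  # thigh oscillation about a standing lean, with a C^2 quintic amplitude
  # envelope over the first and last stride so angular acceleration is
  # continuous at gait initiation/termination
  th_mid <- deg2rad(5)
  ea <- .h5(clamp(u, 0, 1))
  eb <- .h5(clamp(n - u, 0, 1))
  da <- as.numeric(u > 0 & u < 1)
  db <- -as.numeric(u > n - 1 & u < n)
  Ev <- ea$v * eb$v
  Ed1 <- ea$d1 * da * eb$v + ea$v * eb$d1 * db
  Ed2 <- ea$d2 * da^2 * eb$v + 2 * ea$d1 * da * eb$d1 * db +
    ea$v * eb$d2 * db^2
  c2 <- cos(2 * pi * u); s2 <- sin(2 * pi * u)
  udot <- as.numeric(active) / Tc
  th_t <- th_mid + At * Ev * c2
  dth_t <- At * (Ed1 * c2 - Ev * 2 * pi * s2) * udot
  ddth_t <- At * (Ed2 * c2 - 2 * Ed1 * 2 * pi * s2 -
                    Ev * (2 * pi)^2 * c2) * udot^2
  knee <- knee_min + sw * knee_rng * fb$v
  dknee <- sw * knee_rng * fb$d1 * sgdot
  ddknee <- sw * knee_rng * fb$d2 * sgdot^2
  th_s <- th_t - knee
  dth_s <- dth_t - dknee
  ddth_s <- ddth_t - ddknee

  y <- if (side == "L") 0.1 else -0.1
  stance_mask <- as.integer(!swing)

  list(side = side, t0 = t0, L = L, h = h,
       knee_min = knee_min, knee_rng = knee_rng,
       foot = list(x = x, y = rep(y, length(t)), z = z,
                   dx = dx, dz = dz, ddx = ddx, ddz = ddz,
                   theta = th_f, dtheta = dth_f),
       thigh = list(theta = th_t, dtheta = dth_t, ddtheta = ddth_t),
       shank = list(theta = th_s, dtheta = dth_s, ddtheta = ddth_s),
       knee = knee, stance = stance_mask, y = y)
}

# quaternion rows for rotation about y by -theta (vectorized)
.quat_about_y <- function(theta) {
  cbind(cos(theta / 2), 0, -sin(theta / 2), 0)
}

# position/velocity/acceleration of a point r along a segment of
# inclination theta(t) hanging from an anchor trajectory
.segment_point <- function(anchor, r, th, dth, ddth) {
  dirx <- sin(th); dirz <- -cos(th)
  list(pos = cbind(anchor$pos[, 1L] + r * dirx, anchor$pos[, 2L],
                   anchor$pos[, 3L] + r * dirz),
       vel = cbind(anchor$vel[, 1L] + r * cos(th) * dth, anchor$vel[, 2L],
                   anchor$vel[, 3L] + r * sin(th) * dth),
       acc = cbind(anchor$acc[, 1L] + r * (cos(th) * ddth - sin(th) * dth^2),
                   anchor$acc[, 2L],
                   anchor$acc[, 3L] + r * (sin(th) * ddth + cos(th) * dth^2)))
}

#' Simulate ground-truth lower-limb gait kinematics
#'
#' Builds smooth foot/shank/thigh trajectories realizing the configured
#' stride length, clearance, cycle, stance windows and knee-flexion profile
#' exactly, for both sides (right side phase-shifted by half a cycle).  The
#' session is: `t_static` seconds of quiet standing, `n_strides` strides per
#' foot, `t_end` seconds standing.
#'
#' @param cfg a [gait_config()].
#' @return object of class `gait_truth`: list with `t`, `segments` (per
#'   segment: `pos`, `vel`, `acc` in the global frame, `quat` rows
#'   sensor-to-global, `omega` body rates), `stance` (0/1 truth masks per
#'   foot), `strides` (per-side data frames of exact per-stride parameters),
#'   `joints` (knee/ankle truth series, rad), `init` (standing segment
#'   inclinations, rad) and `cfg`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "gait_config"))
  Tc <- cfg$cycle_s
  duration <- cfg$t_static + (cfg$n_strides + 0.5) * Tc + cfg$t_end
  t <- seq(0, duration, by = 1 / cfg$fs)
  nT <- length(t)
  kinL <- .side_kinematics(t, cfg, "L")
  kinR <- .side_kinematics(t, cfg, "R")

  segments <- list()
  stance <- list()
  strides <- list()
  joints <- list()
  init <- list()
  zero <- matrix(0, nT, 3L)

  for (kin in list(kinL, kinR)) {
    sd <- kin$side
    f <- kin$foot
    foot_pos <- cbind(f$x, f$y, f$z)
    foot_vel <- cbind(f$dx, 0, f$dz)
    foot_acc <- cbind(f$ddx, 0, f$ddz)
    segments[[paste0("foot_", sd)]] <- list(
      pos = foot_pos, vel = foot_vel, acc = foot_acc,
      quat = .quat_about_y(f$theta),
      omega = cbind(0, -f$dtheta, 0))
    stance[[paste0("foot_", sd)]] <- kin$stance
  }

  # hip: midpoint of the feet horizontally, constant height
  hip <- list(
    pos = cbind((segments$foot_L$pos[, 1L] + segments$foot_R$pos[, 1L]) / 2,
                0, 0.95),
    vel = cbind((segments$foot_L$vel[, 1L] + segments$foot_R$vel[, 1L]) / 2,
                0, 0),
    acc = cbind((segments$foot_L$acc[, 1L] + segments$foot_R$acc[, 1L]) / 2,
                0, 0))
  r_thigh <- 0.25; l_thigh <- 0.45; r_shank <- 0.25

  for (kin in list(kinL, kinR)) {
    sd <- kin$side
    th <- kin$thigh; sh <- kin$shank
    side_hip <- hip
    side_hip$pos <- cbind(hip$pos[, 1L], kin$y, hip$pos[, 3L])
    tp <- .segment_point(side_hip, r_thigh, th$theta, th$dtheta, th$ddtheta)
    knee_anchor <- .segment_point(side_hip, l_thigh, th$theta, th$dtheta,
                                  th$ddtheta)
    sp <- .segment_point(knee_anchor, r_shank, sh$theta, sh$dtheta,
                         sh$ddtheta)
    segments[[paste0("thigh_", sd)]] <- list(
      pos = tp$pos, vel = tp$vel, acc = tp$acc,
      quat = .quat_about_y(th$theta),
      omega = cbind(0, -th$dtheta, 0))
    segments[[paste0("shank_", sd)]] <- list(
      pos = sp$pos, vel = sp$vel, acc = sp$acc,
      quat = .quat_about_y(sh$theta),
      omega = cbind(0, -sh$dtheta, 0))

    ic <- kin$t0 + (0:(cfg$n_strides - 1L)) * Tc
    strides[[sd]] <- data.frame(
      stride = seq_len(cfg$n_strides),
      ic = ic,
      cycle = Tc,
      stance_time = cfg$stance_fraction * Tc,
      swing_time = (1 - cfg$stance_fraction) * Tc,
      length = kin$L,
      speed = kin$L / Tc,
      clearance = kin$h,
      knee_rom = rad2deg(kin$knee_rng))

    f0 <- kin$foot$theta[1L]; s0 <- kin$shank$theta[1L]
    joints[[paste0("knee_", sd)]] <- kin$knee
    joints[[paste0("ankle_", sd)]] <- (kin$shank$theta - kin$foot$theta) -
      (s0 - f0)
    init[[sd]] <- list(thigh0 = kin$thigh$theta[1L], shank0 = s0, foot0 = f0)
  }

  structure(list(t = t, fs = cfg$fs, segments = segments, stance = stance,
                 strides = strides, joints = joints, init = init, cfg = cfg),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("gait truth: %d strides/side, %.1f s at %g Hz, %d segments\n",
              x$cfg$n_strides, diff(range(x$t)), x$fs, length(x$segments)))
  invisible(x)
}

# vectorized rotate rows of V by conjugate of quaternion rows (global->sensor)
.rotate_rows_inv <- function(Q, V) {
  q0 <- Q[, 1L]; q1 <- -Q[, 2L]; q2 <- -Q[, 3L]; q3 <- -Q[, 4L]
  vx <- V[, 1L]; vy <- V[, 2L]; vz <- V[, 3L]
  cbind((1 - 2 * (q2^2 + q3^2)) * vx + 2 * (q1 * q2 - q0 * q3) * vy +
          2 * (q1 * q3 + q0 * q2) * vz,
        2 * (q1 * q2 + q0 * q3) * vx + (1 - 2 * (q1^2 + q3^2)) * vy +
          2 * (q2 * q3 - q0 * q1) * vz,
        2 * (q1 * q3 - q0 * q2) * vx + 2 * (q2 * q3 + q0 * q1) * vy +
          (1 - 2 * (q1^2 + q2^2)) * vz)
}

#' Synthesize raw IMU streams from ground-truth kinematics
#'
#' Sensor-frame specific force `R' (a_lin + g)` is distorted by the forward
#' misalignment matrix and white noise; gyroscope output is the body rate
#' plus a constant per-axis bias (drawn per sensor) and white noise; the
#' magnetometer sees `soft_iron (R' B) + hard_iron` plus noise.  Fixed seeds
#' give bit-identical output.
#'
#' @param truth a [simulate_truth()] result.
#' @param err a [sensor_error_model()].
#' @param g gravity magnitude (m/s^2).
#' @return named list of [imu_sequence()] objects, one per segment.
#' @export
synthesize_imu <- function(truth, err, g = STANDARD_GRAVITY) {
  stopifnot(inherits(truth, "gait_truth"), inherits(err, "sensor_error_model"))
  E <- nonortho_matrix(err$nonortho)
  B <- truth$cfg$mag_field
  n <- length(truth$t)
  out <- list()
  segs <- names(truth$segments)
  for (idx in seq_along(segs)) {
    nm <- segs[idx]
    seg <- truth$segments[[nm]]
    grav <- matrix(rep(c(0, 0, g), each = n), n, 3L)
    f_sensor <- .rotate_rows_inv(seg$quat, seg$acc + grav)
    m_sensor <- .rotate_rows_inv(seg$quat, matrix(rep(B, each = n), n, 3L))
    draws <- with_seed(err$seed * 131L + idx, {
      list(bias = stats::rnorm(3L, 0, err$gyro_bias),
           na = matrix(stats::rnorm(3L * n, 0, err$accel_noise_sd), n, 3L),
           ng = matrix(stats::rnorm(3L * n, 0, err$gyro_noise_sd), n, 3L),
           nm = matrix(stats::rnorm(3L * n, 0, err$mag_noise_sd), n, 3L))
    })
    acc <- f_sensor %*% t(E) + draws$na
    gyro <- sweep(seg$omega, 2L, -draws$bias) + draws$ng
    mag <- m_sensor %*% t(err$soft_iron) +
      matrix(rep(err$hard_iron, each = n), n, 3L) + draws$nm
    out[[nm]] <- imu_sequence(truth$t, acc, gyro, mag = mag, fs = truth$fs,
                              segment = nm)
  }
  out
}

#' Static multi-orientation accelerometer calibration cloud
#'
#' Quasi-uniform orientation coverage of the gravity vector (Fibonacci
#' sphere) pushed through the misalignment forward model, with `n_per` noisy
#' samples per orientation.
#'
#' @param err a [sensor_error_model()].
#' @param n_orient number of orientations (>= 20).
#' @param n_per samples per orientation.  The defaults give 6000 samples (a
#'   one-minute capture at 100 Hz spread over 60 orientations, about one
#'   second per pose): misalignment estimation is noise-limited, and its
#'   residual both multiplies swing-phase accelerations and tilts the
#'   gravity reference downstream — a tilt bias of angle delta leaks
#'   delta x stride-length of vertical error per stride, which no
#'   zero-velocity update can remove — so a sparse cloud turns directly
#'   into position drift.
#' @param g gravity magnitude (m/s^2).
#' @return (n_orient * n_per) x 3 matrix of raw accelerometer samples.
#' @export
static_orientation_cloud <- function(err, n_orient = 60L, n_per = 100L,
                                     g = STANDARD_GRAVITY) {
  if (n_orient < 20L) stopf("n_orient must be >= 20 for adequate coverage")
  i <- seq_len(n_orient) - 0.5
  phi <- acos(1 - 2 * i / n_orient)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  E <- nonortho_matrix(err$nonortho)
  pts <- (g * dirs[rep(seq_len(n_orient), each = n_per), ]) %*% t(E)
  with_seed(err$seed * 131L + 101L, {
    pts + matrix(stats::rnorm(length(pts), 0, err$accel_noise_sd),
                 nrow(pts), 3L)
  })
}

#' Figure-eight magnetometer calibration sweep
#'
#' Emulates rotating the node along a figure-eight trajectory: the
#' sensor-frame field direction follows a Lissajous path covering well beyond
#' a hemisphere, distorted by the soft/hard-iron model plus noise.
#'
#' @param err a [sensor_error_model()].
#' @param field global field vector (arbitrary units).
#' @param n number of samples along the sweep; the default corresponds to a
#'   realistic 30 s capture at 100 Hz (several figure-eight passes).  The
#'   soft-iron axes — and through them the heading reference — are
#'   noise-limited, so short sweeps leave a constant azimuth bias that turns
#'   into lateral position drift downstream.
#' @return n x 3 matrix of raw magnetometer samples.
#' @export
figure_eight_sweep <- function(err, field = c(22, 0, -40), n = 3000L) {
  s <- seq(0, 1, length.out = n)
  lat <- deg2rad(75) * sin(6 * pi * s)
  lon <- 4 * pi * s
  dirs <- cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  m_true <- norm3(field) * dirs
  raw <- m_true %*% t(err$soft_iron) +
    matrix(rep(err$hard_iron, each = n), n, 3L)
  with_seed(err$seed * 131L + 102L, {
    raw + matrix(stats::rnorm(length(raw), 0, err$mag_noise_sd), n, 3L)
  })
}

#' Simulate a complete capture session
#'
#' Bundles ground truth, raw sensor streams and calibration captures
#' (static orientation cloud + figure-eight sweep) the way a real recording
#' session would provide them; the result feeds [run_pipeline()] directly.
#'
#' @param cfg a [gait_config()].
#' @param err a [sensor_error_model()]; defaults to the model seeded from
#'   `cfg$seed`.
#' @return object of class `gait_session` with elements `sequences`,
#'   `calibration` (`accel_cloud`, `mag_sweep`), `truth`, `cfg`, `err`.
#' @export
simulate_session <- function(cfg = gait_config(),
                             err = sensor_error_model(seed = cfg$seed)) {
  truth <- simulate_truth(cfg)
  structure(list(sequences = synthesize_imu(truth, err),
                 calibration = list(
                   accel_cloud = static_orientation_cloud(err),
                   mag_sweep = figure_eight_sweep(err,
                                                  field = cfg$mag_field)),
                 truth = truth, cfg = cfg, err = err),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("gait session: %d sensor streams, %d strides/side, seed %d\n",
              length(x$sequences), x$cfg$n_strides, x$err$seed))
  invisible(x)
}

#' Write a session's sensor logs and calibration captures to a directory
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(session$sequences))
    write_imu_log(session$sequences[[nm]], file.path(dir, paste0(nm, ".csv")))
  utils::write.csv(as.data.frame(session$calibration$accel_cloud) |>
                     stats::setNames(c("x", "y", "z")),
                   file.path(dir, "accel_cloud.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(session$calibration$mag_sweep) |>
                     stats::setNames(c("x", "y", "z")),
                   file.path(dir, "mag_sweep.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
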