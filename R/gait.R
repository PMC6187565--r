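# ZVU-aided strapdown integration and spatio-temporal gait parameters.

#' Remove gravity from accelerometer data
#'
#' Rotates sensor-frame specific force into the global frame with the
#' attitude trajectory and subtracts the gravity vector `(0, 0, g)`, leaving
#' global linear acceleration.
#'
#' @param acc n x 3 sensor-frame specific force (m/s^2).
#' @param quats n x 4 quaternion trajectory (sensor to global).
#' @param g gravity magnitude (m/s^2).
#' @return n x 3 global linear acceleration.
#' @export
remove_gravity <- function(acc, quats, g = STANDARD_GRAVITY) {
  acc <- as_matrix3(acc, "acc")
  if (nrow(acc) != nrow(quats))
    stopf("acc and quats must have the same number of samples")
  q0 <- quats[, 1L]; q1 <- quats[, 2L]; q2 <- quats[, 3L]; q3 <- quats[, 4L]
  vx <- acc[, 1L]; vy <- acc[, 2L]; vz <- acc[, 3L]
  out <- cbind(
    (1 - 2 * (q2^2 + q3^2)) * vx + 2 * (q1 * q2 - q0 * q3) * vy +
      2 * (q1 * q3 + q0 * q2) * vz,
    2 * (q1 * q2 + q0 * q3) * vx + (1 - 2 * (q1^2 + q3^2)) * vy +
      2 * (q2 * q3 - q0 * q1) * vz,
    2 * (q1 * q3 - q0 * q2) * vx + 2 * (q2 * q3 + q0 * q1) * vy +
      (1 - 2 * (q1^2 + q2^2)) * vz)
  out[, 3L] <- out[, 3L] - g
  out
}

#' Zero-velocity-aided double integration of linear acceleration
#'
#' Trapezoidal integration of global linear acceleration to velocity, with
#' velocity pinned to zero inside every stance (ZVU) interval.  The residual
#' velocity that has accumulated when a stance begins is redistributed
#' linearly backward over the preceding swing (the standard ZUPT de-drift:
#' it exactly cancels the position error of any constant acceleration bias
#' over the swing), then velocity is integrated once more to position.
#'
#' @param lin_acc n x 3 global linear acceleration (from [remove_gravity()]).
#' @param mask a `stance_mask` aligned to `lin_acc`.
#' @param fs sampling rate (Hz); used when `t` is not given.
#' @param t optional sample times (s).
#' @param guard samples eroded from each end of every stance interval before
#'   velocity is pinned to zero, guarding against detection-edge samples
#'   where the foot still moves slightly; intervals are never eroded below 3
#'   samples.
#' @return list with `velocity` and `position` (n x 3 matrices, position
#'   relative to the first sample).
#' @export
integrate_position_zvu <- function(lin_acc, mask, fs = NULL, t = NULL,
                                   guard = 5L) {
  a <- as_matrix3(lin_acc, "lin_acc")
  n <- nrow(a)
  iv <- if (inherits(mask, "stance_mask")) mask$intervals else zvu_intervals(mask)
  if (inherits(mask, "stance_mask") && length(mask$mask) != n)
    stopf("mask and lin_acc lengths differ")
  if (guard > 0L && nrow(iv) > 0L) {
    for (r in seq_len(nrow(iv))) {
      gmax <- max(0L, (iv[r, "end"] - iv[r, "start"] - 3L) %/% 2L)
      gg <- min(as.integer(guard), gmax)
      iv[r, "start"] <- iv[r, "start"] + gg
      iv[r, "end"] <- iv[r, "end"] - gg
    }
  }
  if (is.null(t)) {
    if (is.null(fs)) stopf("either fs or t must be supplied")
    t <- (seq_len(n) - 1L) / fs
  }
  if (nrow(iv) >= 2L) {
    gaps <- t[iv[-1L, "start"]] - t[pmin(iv[-nrow(iv), "end"], n)]
    if (any(gaps > 5))
      warnf("more than 5 s without a zero-velocity update: expect drift")
  } else if (nrow(iv) <= 1L && diff(range(t)) > 5) {
    warnf("more than 5 s without a zero-velocity update: expect drift")
  }
  v_raw <- pracma::cumtrapz(t, a)
  v <- v_raw
  # zero inside stance; re-reference and de-drift each inter-stance segment
  if (nrow(iv) > 0L) {
    for (r in seq_len(nrow(iv))) {
      rows <- iv[r, "start"]:(iv[r, "end"] - 1L)
      v[rows, ] <- 0
    }
    bounds <- rbind(cbind(prev_end = 0L, next_start = iv[1L, "start"]),
                    if (nrow(iv) > 1L)
                      cbind(prev_end = iv[-nrow(iv), "end"] - 1L,
                            next_start = iv[-1L, "start"]),
                    cbind(prev_end = iv[nrow(iv), "end"] - 1L,
                          next_start = n + 1L))
    for (r in seq_len(nrow(bounds))) {
      j0 <- bounds[r, "prev_end"] + 1L       # first swing row
      j1 <- bounds[r, "next_start"] - 1L     # last swing row
      if (j0 > j1) next
      ref <- if (bounds[r, "prev_end"] >= 1L) v_raw[bounds[r, "prev_end"], ] else c(0, 0, 0)
      seg <- sweep(v_raw[j0:j1, , drop = FALSE], 2L, ref)
      if (bounds[r, "next_start"] <= n) {
        resid <- v_raw[bounds[r, "next_start"], ] - ref
        t_ref <- if (bounds[r, "prev_end"] >= 1L) t[bounds[r, "prev_end"]] else t[j0]
        frac <- (t[j0:j1] - t_ref) / (t[bounds[r, "next_start"]] - t_ref)
        seg <- seg - outer(frac, resid)
      }
      v[j0:j1, ] <- seg
    }
  }
  p <- pracma::cumtrapz(t, v)
  list(velocity = v, position = p)
}

#' Segment a position trace into strides
#'
#' Initial contact (IC) is the start of each stance interval and foot-off
#' (FO) its end; one stride spans consecutive ICs of the same foot.  Stride
#' length is the horizontal displacement between the componentwise median
#' positions of the bounding stance intervals (medians are robust to
#' integration ringing); clearance is the peak vertical position during
#' swing above the mean vertical position of the bounding stances.
#'
#' @param mask a `stance_mask`.
#' @param positions n x 3 global position trace (m).
#' @param fs sampling rate (Hz); used when `t` is not given.
#' @param t optional sample times (s).
#' @return data frame with one row per stride: `start_ic`, `end_ic`,
#'   `cycle`, `stance_time`, `swing_time`, `length`, `speed`,
#'   `clearance_max`.
#' @export
segment_strides <- function(mask, positions, fs = NULL, t = NULL) {
  pos <- as_matrix3(positions, "positions")
  iv <- mask$intervals
  n <- nrow(pos)
  if (is.null(t)) {
    if (is.null(fs)) fs <- mask$fs
    t <- (seq_len(n) - 1L) / fs
  }
  if (nrow(iv) < 2L) {
    warnf("fewer than 2 stance intervals: no strides to segment")
    return(data.frame(start_ic = numeric(), end_ic = numeric(),
                      cycle = numeric(), stance_time = numeric(),
                      swing_time = numeric(), length = numeric(),
                      speed = numeric(), clearance_max = numeric()))
  }
  med_pos <- t(apply(iv, 1L, function(r) {
    apply(pos[r["start"]:(r["end"] - 1L), , drop = FALSE], 2L, stats::median)
  }))
  out <- lapply(seq_len(nrow(iv) - 1L), function(k) {
    ic1 <- t[iv[k, "start"]]
    ic2 <- t[iv[k + 1L, "start"]]
    fo <- t[min(iv[k, "end"], n)]
    cycle <- ic2 - ic1
    stance <- fo - ic1
    len <- sqrt(sum((med_pos[k + 1L, 1:2] - med_pos[k, 1:2])^2))
    swing_rows <- iv[k, "end"]:(iv[k + 1L, "start"] - 1L)
    baseline <- mean(med_pos[k:(k + 1L), 3L])
    clr <- max(pos[swing_rows, 3L]) - baseline
    data.frame(start_ic = ic1, end_ic = ic2, cycle = cycle,
               stance_time = stance, swing_time = cycle - stance,
               length = len, speed = len / cycle, clearance_max = clr)
  })
  do.call(rbind, out)
}

#' Sagittal inclination of a segment from a static accelerometer capture
#'
#' For a resting sensor reading `(g sin theta, 0, g cos theta)` the
#' inclination relative to gravity is `atan2(ax, az)`.
#'
#' @param static_acc a 3-vector or n x 3 matrix of near-static samples
#'   (m/s^2); matrices are averaged.
#' @param g gravity magnitude (m/s^2).
#' @param tol relative tolerance on `| ||a|| - g | / g` for the static check.
#' @return inclination angle (rad), positive toward the sensor +x axis.
#' @export
initial_segment_angle <- function(static_acc, g = STANDARD_GRAVITY,
                                  tol = 0.05) {
  m <- as_matrix3(static_acc, "static_acc")
  a <- colMeans(m)
  if (abs(norm3(a) - g) / g > tol)
    stopf("input is not static: mean specific force %.3f differs from g", norm3(a))
  atan2(a[1L], a[3L])
}

# linear resampling of one sequence's channels onto a target time grid
.resample_seq <- function(seq, t_target) {
  if (max(abs(range(seq$t)[1] - t_target[1]),
          abs(range(seq$t)[2] - t_target[length(t_target)])) > 0.01 + 1e-9)
    stopf("sequences misaligned by more than 10 ms after resampling")
  resample_mat <- function(m)
    apply(m, 2L, function(col) stats::approx(seq$t, col, t_target,
                                             rule = 2)$y)
  out <- seq
  out$t <- t_target
  out$acc <- resample_mat(seq$acc)
  out$gyro <- resample_mat(seq$gyro)
  if (!is.null(seq$mag)) out$mag <- resample_mat(seq$mag)
  out
}

#' Knee flexion angle from thigh and shank gyroscopes
#'
#' Integrates the relative angular rate of thigh and shank about the flexion
#' axis and adds the initial inclination difference:
#' `theta_knee(t) = int (omega_thigh - omega_shank) . axis dt +
#' theta_thigh0 - theta_shank0`.  When stance intervals are supplied the
#' integral is re-anchored to the initial value at each stance midpoint
#' (knee near its standing flexion in mid-stance), which bounds gyro drift
#' to a single stride.
#'
#' @param thigh,shank [imu_sequence()] objects on a common clock (the shank
#'   is linearly resampled onto the thigh grid; an offset above 10 ms is an
#'   error).
#' @param init list with `theta_thigh0` and `theta_shank0` (rad), from
#'   [initial_segment_angle()].
#' @param stance optional `stance_mask` (same side's foot) for per-stride
#'   drift resets.
#' @param axis flexion axis in sensor coordinates (unit 3-vector).  The
#'   default `(0, -1, 0)` matches a mediolateral-y mounting with inclination
#'   positive toward +x.
#' @return numeric vector of knee flexion (rad, positive = flexion), with
#'   attribute `t`.
#' @export
knee_angle <- function(thigh, shank, init, stance = NULL,
                       axis = c(0, -1, 0)) {
  shank_r <- .resample_seq(shank, thigh$t)
  w_rel <- drop((thigh$gyro - shank_r$gyro) %*% axis)
  theta0 <- init$theta_thigh0 - init$theta_shank0
  theta <- drop(pracma::cumtrapz(thigh$t, w_rel)) + theta0
  theta <- .reset_at_stance_mid(theta, stance, theta0)
  attr(theta, "t") <- thigh$t
  theta
}

#' Ankle angle from foot and shank gyroscopes
#'
#' Foot-shank analog of [knee_angle()], integrating
#' `(omega_shank - omega_foot) . axis` so dorsiflexion (shank rotating
#' forward over the foot) is positive and plantarflexion negative.
#'
#' @param foot,shank [imu_sequence()] objects on a common clock.
#' @param init list with `theta_ankle0`, the standing ankle angle (rad,
#'   default 0).
#' @param stance optional `stance_mask` for per-stride drift resets.
#' @param axis flexion axis (unit 3-vector), as in [knee_angle()].
#' @return numeric vector of ankle angle (rad), attribute `t`.
#' @export
ankle_angle <- function(foot, shank, init = list(theta_ankle0 = 0),
                        stance = NULL, axis = c(0, -1, 0)) {
  foot_r <- .resample_seq(foot, shank$t)
  w_rel <- drop((shank$gyro - foot_r$gyro) %*% axis)
  theta0 <- init$theta_ankle0
  theta <- drop(pracma::cumtrapz(shank$t, w_rel)) + theta0
  theta <- .reset_at_stance_mid(theta, stance, theta0)
  attr(theta, "t") <- shank$t
  theta
}

.reset_at_stance_mid <- function(theta, stance, theta_ref) {
  if (is.null(stance)) return(theta)
  iv <- if (inherits(stance, "stance_mask")) stance$intervals else stance
  n <- length(theta)
  for (r in seq_len(nrow(iv))) {
    mid <- (iv[r, "start"] + iv[r, "end"] - 1L) %/% 2L
    if (mid < 1L || mid > n) next
    theta[mid:n] <- theta[mid:n] - (theta[mid] - theta_ref)
  }
  theta
}

#' Per-stride knee range of motion
#'
#' Max minus min of the flexion series within each stride window, in
#' degrees; invariant to constant offsets.
#'
#' @param theta_knee flexion series (rad) as returned by [knee_angle()].
#' @param strides stride table from [segment_strides()] (uses `start_ic` /
#'   `end_ic`), or an integer matrix of half-open sample ranges.
#' @param t sample times; taken from `attr(theta_knee, "t")` when missing.
#' @return numeric vector, one ROM (deg) per stride.
#' @export
knee_rom <- function(theta_knee, strides, t = attr(theta_knee, "t")) {
  if (is.matrix(strides)) {
    ranges <- strides
  } else {
    if (is.null(t)) stopf("sample times required to window the strides")
    ranges <- cbind(findInterval(strides$start_ic, t),
                    findInterval(strides$end_ic, t))
  }
  apply(ranges, 1L, function(r) {
    seg <- theta_knee[r[1L]:min(r[2L], length(theta_knee))]
    rad2deg(max(seg) - min(seg))
  })
}

#' Spatio-temporal gait parameters with summary statistics
#'
#' Assembles the per-stride parameter table (stride length, speed, cadence,
#' cycle, stance/swing time, clearance, and optionally knee ROM) and its
#' mean +/- SD summary.  Cadence counts steps: `120 / cycle` steps per
#' minute (two steps per stride).  Strides bordering standstill (gait
#' initiation/termination) are excluded by a robust rule: cycle or stance
#' time deviating more than 25 % from the session median.
#'
#' @param strides stride table from [segment_strides()].
#' @param knee_rom_deg optional per-stride knee ROM (deg), aligned to
#'   `strides` rows.
#' @param drop_outliers apply the steady-state stride selection (default
#'   `TRUE`).
#' @return object of class `gait_parameters`: list with `strides` (per-stride
#'   data frame) and `summary` (parameter, mean, sd).
#' @export
compute_gait_parameters <- function(strides, knee_rom_deg = NULL,
                                    drop_outliers = TRUE) {
  if (nrow(strides) < 1L) stopf("at least one stride is required")
  df <- strides
  df$stride_frequency <- 120 / df$cycle
  if (!is.null(knee_rom_deg)) {
    if (length(knee_rom_deg) != nrow(df))
      stopf("knee_rom_deg must align with the stride table")
    df$knee_rom <- knee_rom_deg
  }
  keep <- rep(TRUE, nrow(df))
  if (drop_outliers && nrow(df) >= 3L) {
    med_cycle <- stats::median(df$cycle)
    med_stance <- stats::median(df$stance_time)
    keep <- abs(df$cycle - med_cycle) <= 0.25 * med_cycle &
      abs(df$stance_time - med_stance) <= 0.25 * med_stance
  }
  df <- df[keep, , drop = FALSE]
  params <- c(stride_length = "length", stride_speed = "speed",
              stride_frequency = "stride_frequency", walking_cycle = "cycle",
              stance_time = "stance_time", swing_time = "swing_time",
              clearance = "clearance_max")
  if (!is.null(knee_rom_deg)) params <- c(params, knee_rom = "knee_rom")
  summ <- data.frame(
    parameter = names(params),
    mean = vapply(params, function(col) mean(df[[col]]), numeric(1L)),
    sd = vapply(params, function(col) stats::sd(df[[col]]), numeric(1L)),
    row.names = NULL)
  structure(list(strides = df, summary = summ), class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf("gait parameters over %d strides (mean +/- SD):\n",
              nrow(x$strides)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %8.3f +/- %.3f\n", s$parameter[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  invisible(x)
}
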