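# Sensor-log containers and delimited-text I/O.

SEGMENT_LABELS <- c("foot_L", "foot_R", "shank_L", "shank_R",
                    "thigh_L", "thigh_R")

#' Construct an IMU sequence
#'
#' A uniformly sampled tri-axial accelerometer/gyroscope (and optionally
#' magnetometer) stream for one body-segment sensor.
#'
#' @param t sample times (s), strictly increasing.
#' @param acc n x 3 accelerometer matrix (m/s^2, sensor frame; specific
#'   force, i.e. +g on the up axis at rest).
#' @param gyro n x 3 gyroscope matrix (rad/s, sensor frame).
#' @param mag optional n x 3 magnetometer matrix (arbitrary field units).
#' @param fs nominal sampling rate (Hz); the median time step must agree with
#'   `1/fs` within 10 %.
#' @param segment body-segment label, one of
#'   `r paste(SEGMENT_LABELS, collapse = ", ")`, or `NA`.
#' @return object of class `imu_sequence`.
#' @export
imu_sequence <- function(t, acc, gyro, mag = NULL, fs = 100,
                         segment = NA_character_) {
  t <- as.numeric(t)
  acc <- as_matrix3(acc, "acc")
  gyro <- as_matrix3(gyro, "gyro")
  if (!is.null(mag)) mag <- as_matrix3(mag, "mag")
  n <- length(t)
  if (nrow(acc) != n || nrow(gyro) != n || (!is.null(mag) && nrow(mag) != n))
    stopf("t, acc, gyro%s must have equal lengths",
          if (is.null(mag)) "" else ", mag")
  if (n < 2L) stopf("an IMU sequence needs at least 2 samples")
  if (!all(is.finite(t)) || any(diff(t) <= 0))
    stopf("t must be finite and strictly increasing")
  if (abs(stats::median(diff(t)) - 1 / fs) > 0.1 / fs)
    stopf("median time step disagrees with 1/fs by more than 10%%")
  if (!is.na(segment) && !segment %in% SEGMENT_LABELS)
    stopf("segment must be one of %s", paste(SEGMENT_LABELS, collapse = ", "))
  structure(list(t = t, acc = acc, gyro = gyro, mag = mag, fs = fs,
                 segment = segment),
            class = "imu_sequence")
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("IMU sequence [%s]: %d samples at %g Hz (%.2f s)%s\n",
              if (is.na(x$segment)) "unlabeled" else x$segment,
              length(x$t), x$fs, diff(range(x$t)),
              if (is.null(x$mag)) "" else ", with magnetometer"))
  invisible(x)
}

#' Read an IMU log from delimited text
#'
#' Expects a header row with columns `t,ax,ay,az,gx,gy,gz` and optionally
#' `mx,my,mz`, SI units (seconds, m/s^2, rad/s).
#'
#' @param path input file (CSV).
#' @param segment optional segment label to attach.
#' @param fs nominal sampling rate; inferred from the median time step when
#'   `NULL`.
#' @return an [imu_sequence()].
#' @export
read_imu_log <- function(path, segment = NA_character_, fs = NULL) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("%s: missing column(s) %s", path, paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(as.matrix(df[need]), 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stopf("%s: non-finite value at data line %d", path, bad[1L])
  if (any(diff(df$t) <= 0)) {
    i <- which(diff(df$t) <= 0)[1L]
    stopf("%s: time not strictly increasing at data line %d", path, i + 1L)
  }
  mag <- NULL
  if (all(c("mx", "my", "mz") %in% names(df)))
    mag <- as.matrix(df[c("mx", "my", "mz")])
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t))
  imu_sequence(df$t, as.matrix(df[c("ax", "ay", "az")]),
               as.matrix(df[c("gx", "gy", "gz")]), mag = mag, fs = fs,
               segment = segment)
}

#' Write an IMU sequence as delimited text
#'
#' Inverse of [read_imu_log()]; the round trip is lossless to full double
#' precision.
#'
#' @param seq an [imu_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_imu_log <- function(seq, path) {
  df <- data.frame(t = seq$t,
                   ax = seq$acc[, 1L], ay = seq$acc[, 2L], az = seq$acc[, 3L],
                   gx = seq$gyro[, 1L], gy = seq$gyro[, 2L], gz = seq$gyro[, 3L])
  if (!is.null(seq$mag)) {
    df$mx <- seq$mag[, 1L]; df$my <- seq$mag[, 2L]; df$mz <- seq$mag[, 3L]
  }
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an attitude trajectory as CSV
#'
#' Columns `t, q0..q3, roll, pitch, yaw` (rad).
#'
#' @param t sample times (s).
#' @param quats n x 4 quaternion matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attitude <- function(t, quats, path) {
  eul <- t(apply(quats, 1L, function(q) unlist(quat_to_euler(q))))
  df <- data.frame(t = t, q0 = quats[, 1L], q1 = quats[, 2L],
                   q2 = quats[, 3L], q3 = quats[, 4L],
                   roll = eul[, 1L], pitch = eul[, 2L], yaw = eul[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
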