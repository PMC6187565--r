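# Stance-phase detection for zero-velocity updating.
#
# Two per-sample criteria are fused: the moving variance of the normalized
# squared acceleration norm (small when the foot rests under gravity only)
# and the windowed angular-rate energy (small when the foot does not rotate).
# Samples passing both thresholds form the stance mask; maximal runs of ones
# are the intervals on which the zero-velocity update is valid.

#' Stance detector configuration
#'
#' @param lambda1 threshold on the moving variance of the acceleration-norm
#'   ratio (dimensionless).  At rest the variance is of order
#'   `(2 sigma_a / g)^2`, orders of magnitude below the default.
#' @param lambda2 threshold on the normalized angular-rate energy.  For
#'   three-axis white gyro noise the energy statistic has expectation 3 at
#'   rest, so the threshold must sit above 3; the default leaves a wide
#'   margin below swing-phase energies (10^3 and larger).
#' @param W angular-rate energy window (samples, >= 3).
#' @param N acceleration variance window (samples, >= 3).
#' @param sigma_omega2 gyroscope noise variance ((rad/s)^2); when `NULL` it is
#'   estimated from the first second of data (initial quiet standing).
#' @param min_stance minimum stance duration (s); shorter detected stance
#'   runs are discarded and shorter swing gaps between stance runs are closed.
#' @return object of class `stance_config`.
#' @export
stance_config <- function(lambda1 = 0.02, lambda2 = 6, W = 7L, N = 7L,
                          sigma_omega2 = NULL, min_stance = 0.1) {
  if (!is_number(lambda1) || lambda1 <= 0 || !is_number(lambda2) || lambda2 <= 0)
    stopf("thresholds lambda1, lambda2 must be positive")
  if (W < 3L || N < 3L) stopf("windows W and N must be >= 3 samples")
  if (!is.null(sigma_omega2) && (!is_number(sigma_omega2) || sigma_omega2 <= 0))
    stopf("sigma_omega2 must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, W = as.integer(W),
                 N = as.integer(N), sigma_omega2 = sigma_omega2,
                 min_stance = min_stance),
            class = "stance_config")
}

#' Squared acceleration norm, normalized by gravity
#'
#' `V = (ax/g)^2 + (ay/g)^2 + (az/g)^2`; equals 1 for a resting sensor.
#'
#' @param acc 3-vector or n x 3 matrix of accelerometer samples (m/s^2).
#' @param g gravity magnitude (m/s^2, > 0).
#' @return scalar or vector of `V` values.
#' @export
accel_norm_ratio <- function(acc, g = STANDARD_GRAVITY) {
  if (!is_number(g) || g <= 0) stopf("g must be positive")
  m <- as_matrix3(acc, "acc")
  v <- rowSums((m / g)^2)
  if (is.null(dim(acc))) v[[1L]] else v
}

#' Trailing moving variance
#'
#' Population variance (1/N weighting) of each trailing window of `N`
#' samples: `M_j = mean((S_i - mean_N)^2)` over `i in (j-N+1)..j`.  The first
#' `N - 1` outputs are `NA` (warm-up).
#'
#' @param series numeric vector, length >= `N`.
#' @param N window length in samples.
#' @return numeric vector of the same length as `series`.
#' @export
moving_variance <- function(series, N) {
  n <- length(series)
  N <- as.integer(N)
  if (N > n) stopf("window N = %d exceeds series length %d", N, n)
  cs <- cumsum(series)
  cs2 <- cumsum(series^2)
  out <- rep(NA_real_, n)
  j <- N:n
  s <- cs[j] - c(0, cs)[j - N + 1L]
  s2 <- cs2[j] - c(0, cs2)[j - N + 1L]
  out[j] <- pmax(s2 / N - (s / N)^2, 0)
  out
}

#' Trailing angular-rate energy
#'
#' `E_j = sum(||omega_i||^2, i in j..j+W-1) / (sigma_omega2 * W)`, assigned to
#' the last sample of its window (trailing alignment), so the first `W - 1`
#' outputs are `NA`.
#'
#' @param gyro n x 3 matrix of angular rates (rad/s).
#' @param W window length in samples.
#' @param sigma_omega2 gyroscope noise variance ((rad/s)^2, > 0).
#' @return numeric vector of length `nrow(gyro)`.
#' @export
gyro_energy <- function(gyro, W, sigma_omega2) {
  g <- as_matrix3(gyro, "gyro")
  if (!is_number(sigma_omega2) || sigma_omega2 <= 0)
    stopf("sigma_omega2 must be positive")
  n <- nrow(g)
  W <- as.integer(W)
  if (W > n) stopf("window W = %d exceeds sequence length %d", W, n)
  sq <- rowSums(g^2)
  cs <- cumsum(sq)
  out <- rep(NA_real_, n)
  j <- W:n
  out[j] <- (cs[j] - c(0, cs)[j - W + 1L]) / (sigma_omega2 * W)
  out
}

# shift a trailing-window statistic so each value sits at its window center
.center_stat <- function(x, width) {
  h <- (as.integer(width) - 1L) %/% 2L
  if (h == 0L) return(x)
  n <- length(x)
  out <- c(x[(h + 1L):n], rep(NA_real_, h))
  out
}

.fill_edge_na <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  if (ok[1L] > 1L) x[seq_len(ok[1L] - 1L)] <- x[ok[1L]]
  last <- ok[length(ok)]
  if (last < n) x[(last + 1L):n] <- x[last]
  x
}

# runs of TRUE as half-open [start, end) index pairs
.runs_true <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect stance phases in a foot-mounted IMU sequence
#'
#' The mask is 1 where the centered moving variance of [accel_norm_ratio()]
#' falls below `lambda1` AND the centered angular-rate energy falls below
#' `lambda2`.  Gyro bias is compensated with the mean over the initial rest
#' second (the same interval used to estimate `sigma_omega2` when it is not
#' supplied).  The raw mask is then cleaned morphologically: swing gaps
#' shorter than `min_stance` are closed and stance runs shorter than
#' `min_stance` removed.
#'
#' Window statistics are computed with the trailing-window primitives
#' [moving_variance()] and [gyro_energy()] and re-centered on their windows,
#' which keeps detected stance onsets/offsets symmetric around the true gait
#' events instead of lagging by a full window.
#'
#' @param seq an [imu_sequence()].
#' @param cfg a [stance_config()].
#' @param g gravity magnitude (m/s^2).
#' @return object of class `stance_mask`: list with `mask` (integer 0/1 per
#'   sample), `intervals` (half-open sample-index ranges, rows `start`,
#'   `end`), `fs`, and the thresholded statistics `var_v` and `energy`.
#' @export
detect_stance <- function(seq, cfg = stance_config(), g = STANDARD_GRAVITY) {
  stopifnot(inherits(seq, "imu_sequence"))
  n <- nrow(seq$acc)
  if (n <= max(cfg$W, cfg$N))
    stopf("sequence shorter than the detector windows")
  n0 <- max(3L, min(n, round(seq$fs)))
  bias <- colMeans(seq$gyro[seq_len(n0), , drop = FALSE])
  gyro_c <- sweep(seq$gyro, 2L, bias)
  s2 <- cfg$sigma_omega2
  if (is.null(s2)) {
    s2 <- mean(apply(seq$gyro[seq_len(n0), , drop = FALSE], 2L, stats::var))
    if (!is.finite(s2) || s2 <= 0) s2 <- 1e-6
  }
  V <- accel_norm_ratio(seq$acc, g)
  mv <- .fill_edge_na(.center_stat(moving_variance(V, cfg$N), cfg$N))
  en <- .fill_edge_na(.center_stat(gyro_energy(gyro_c, cfg$W, s2), cfg$W))
  mask <- as.integer(mv < cfg$lambda1 & en < cfg$lambda2)
  min_run <- max(1L, round(cfg$min_stance * seq$fs))
  # close short swing gaps, then drop short stance runs
  r <- rle(mask)
  inner <- which(r$values == 0L & r$lengths < min_run)
  inner <- inner[inner > 1L & inner < length(r$values)]
  if (length(inner)) {
    r$values[inner] <- 1L
    mask <- inverse.rle(r)
    r <- rle(mask)
  }
  short1 <- which(r$values == 1L & r$lengths < min_run)
  if (length(short1)) {
    r$values[short1] <- 0L
    mask <- inverse.rle(r)
  }
  intervals <- .runs_true(mask == 1L)
  if (nrow(intervals) == 0L)
    warnf("no stance interval detected; zero-velocity updates unavailable")
  structure(list(mask = mask, intervals = intervals, fs = seq$fs,
                 sigma_omega2 = s2, gyro_bias = bias,
                 var_v = mv, energy = en),
            class = "stance_mask")
}

#' @export
print.stance_mask <- function(x, ...) {
  cat(sprintf("stance mask: %d samples at %g Hz, %d stance interval(s)\n",
              length(x$mask), x$fs, nrow(x$intervals)))
  invisible(x)
}

#' Zero-velocity-update intervals of a stance mask
#'
#' @param mask a `stance_mask` (or a plain 0/1 vector).
#' @return integer matrix of half-open `[start, end)` sample-index ranges,
#'   one row per maximal run of ones.
#' @export
zvu_intervals <- function(mask) {
  m <- if (inherits(mask, "stance_mask")) mask$mask else mask
  .runs_true(m == 1L)
}

#' Export a stance mask as delimited text
#'
#' Writes `sample_index,stance_flag` per sample to `mask_path` and, when
#' `intervals_path` is given, `start_s,end_s` per interval.
#'
#' @param mask a `stance_mask`.
#' @param mask_path output CSV for the per-sample mask.
#' @param intervals_path optional output CSV for the intervals (seconds).
#' @return `mask_path`, invisibly.
#' @export
write_stance_mask <- function(mask, mask_path, intervals_path = NULL) {
  utils::write.csv(data.frame(sample_index = seq_along(mask$mask) - 1L,
                              stance_flag = mask$mask),
                   mask_path, row.names = FALSE, quote = FALSE)
  if (!is.null(intervals_path)) {
    iv <- data.frame(start_s = (mask$intervals[, "start"] - 1L) / mask$fs,
                     end_s = (mask$intervals[, "end"] - 1L) / mask$fs)
    utils::write.csv(iv, intervals_path, row.names = FALSE, quote = FALSE)
  }
  invisible(mask_path)
}
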