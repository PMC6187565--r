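test_that("gravity removal recovers global linear acceleration", {
  n <- 100
  q_id <- matrix(rep(quat_identity(), each = n), n, 4)
  still <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  expect_lt(max(abs(remove_gravity(still, q_id))), 1e-12)
  # free fall: zero specific force maps to -g
  ff <- remove_gravity(matrix(0, n, 3), q_id)
  expect_equal(ff[1, ], c(0, 0, -9.81))
  expect_error(remove_gravity(still[1:10, ], q_id), "same number")
  # simulator trace with true attitude matches true linear acceleration
  s <- noiseless_session(n_strides = 4)
  seg <- s$truth$segments$foot_L
  lin <- remove_gravity(s$sequences$foot_L$acc, seg$quat)
  expect_lt(max(abs(lin - seg$acc)), 1e-9)
})

test_that("ZVU integration pins stationary traces and recovers strides", {
  # stationary: displacement below a millimeter
  s <- default_session(n_strides = 3, noise_seed = 11)
  seq <- s$sequences$foot_L
  n <- round(2 * seq$fs)
  still <- imu_sequence(seq$t[1:n], seq$acc[1:n, ], seq$gyro[1:n, ],
                        fs = seq$fs)
  mask <- detect_stance(still)
  lin <- remove_gravity(still$acc, fuse_sequence(still, fusion_config(),
                                                 static_mask = mask$mask == 1))
  kin <- integrate_position_zvu(lin, mask, t = still$t)
  expect_lt(sqrt(sum(kin$position[n, ]^2)), 1e-3)
})

test_that("stride length is recovered and ZVU strictly helps", {
  # noiseless short walk
  sn <- noiseless_session(n_strides = 3)
  rep_n <- run_pipeline(sn)
  lens <- rep_n$parameters$L$strides$length
  expect_true(all(abs(lens - 1.21) < 0.02))
  # noisy walks across seeds
  errs <- sapply(1:10, function(seed) {
    s <- default_session(n_strides = 3, noise_seed = seed)
    r <- run_pipeline(s)
    max(abs(r$parameters$L$strides$length - 1.21))
  })
  expect_lt(max(errs), 0.05)
  # disabling the zero-velocity update must hurt, every seed
  for (seed in 1:3) {
    s <- default_session(n_strides = 5, noise_seed = seed)
    angles <- estimate_nonortho_angles(
      fit_ellipsoid(s$calibration$accel_cloud))
    mag_cal <- calibrate_magnetometer(s$calibration$mag_sweep)
    seq <- s$sequences$foot_L
    seq$acc <- correct_accel(seq$acc, angles, exact = TRUE)
    seq$mag <- apply_mag_calibration(seq$mag, mag_cal)
    seq$gyro <- sweep(seq$gyro, 2,
                      colMeans(seq$gyro[seq_len(100), , drop = FALSE]))
    mask <- detect_stance(seq)
    quats <- fuse_sequence(seq, fusion_config(), static_mask = mask$mask == 1)
    lin <- remove_gravity(seq$acc, quats)
    with_zvu <- integrate_position_zvu(lin, mask, t = seq$t)$position
    no_zvu <- pracma::cumtrapz(seq$t, pracma::cumtrapz(seq$t, lin))
    tru <- s$truth$segments$foot_L$pos
    tru <- sweep(tru, 2, tru[1, ])
    rmse <- function(p) sqrt(mean(rowSums((p - tru)^2)))
    expect_lt(rmse(with_zvu), rmse(no_zvu))
  }
})

test_that("stride segmentation yields consistent cycle decompositions", {
  s <- default_session(n_strides = 10, noise_seed = 12)
  r <- run_pipeline(s)
  st <- r$feet$foot_L$strides
  expect_gte(nrow(st), 9)
  expect_equal(st$cycle, st$stance_time + st$swing_time, tolerance = 1e-12)
  expect_equal(st$speed, st$length / st$cycle, tolerance = 1e-12)
  # left/right relabeling permutes outputs only
  s2 <- s
  s2$sequences <- s$sequences[c("foot_R", "foot_L", "shank_R", "shank_L",
                                "thigh_R", "thigh_L")]
  names(s2$sequences) <- c("foot_L", "foot_R", "shank_L", "shank_R",
                           "thigh_L", "thigh_R")
  r2 <- run_pipeline(s2)
  expect_equal(r2$parameters$L$summary$mean, r$parameters$R$summary$mean,
               tolerance = 1e-12)
  expect_equal(r2$parameters$R$summary$mean, r$parameters$L$summary$mean,
               tolerance = 1e-12)
})

test_that("initial segment inclination comes from static gravity components", {
  expect_equal(initial_segment_angle(c(0, 0, 9.81)), 0)
  a10 <- c(9.81 * sin(10 * pi / 180), 0, 9.81 * cos(10 * pi / 180))
  expect_equal(initial_segment_angle(a10) * 180 / pi, 10, tolerance = 1e-6)
  set.seed(33)
  errs <- sapply(1:20, function(i) {
    noisy <- matrix(rep(a10, each = 100), 100, 3) +
      matrix(stats::rnorm(300, sd = 0.02), 100, 3)
    abs(initial_segment_angle(noisy) * 180 / pi - 10)
  })
  expect_lt(max(errs), 0.2)
  expect_error(initial_segment_angle(c(5, 0, 2)), "not static")
})

test_that("knee angle integrates the thigh-shank rate difference", {
  # identical rates: constant at the initial difference
  n <- 200; fs <- 100
  t <- (0:(n - 1)) / fs
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  gyro <- cbind(0, sin(2 * pi * t), 0)
  thigh <- imu_sequence(t, acc, gyro, fs = fs)
  shank <- imu_sequence(t, acc, gyro, fs = fs)
  init <- list(theta_thigh0 = 0.20, theta_shank0 = 0.05)
  th <- knee_angle(thigh, shank, init)
  expect_equal(unclass(th), rep(0.15, n), tolerance = 1e-12,
               ignore_attr = TRUE)
  # 10 deg/s relative rate for 2 s on top of 5 deg initial: ends at 25 deg
  rate <- 10 * pi / 180
  thigh2 <- imu_sequence(t, acc, matrix(rep(c(0, -rate, 0), each = n), n, 3), fs = fs)
  shank2 <- imu_sequence(t, acc, matrix(0, n, 3), fs = fs)
  init2 <- list(theta_thigh0 = 5 * pi / 180, theta_shank0 = 0)
  th2 <- knee_angle(thigh2, shank2, init2)
  expect_equal(th2[n] * 180 / pi, 5 + 10 * t[n], tolerance = 1e-6)
})

test_that("simulated knee and ankle profiles are recovered", {
  s <- default_session(n_strides = 8, noise_seed = 13)
  r <- run_pipeline(s)
  tr <- s$truth
  # compare over the steady part of the walk
  sel <- which(tr$t > 4 & tr$t < max(tr$t) - 2)
  knee_err <- (r$joints$knee_L[sel] - tr$joints$knee_L[sel]) * 180 / pi
  expect_lt(sqrt(mean(knee_err^2)), 2)
  ankle_err <- (r$joints$ankle_L[sel] - tr$joints$ankle_L[sel]) * 180 / pi
  expect_lt(sqrt(mean(ankle_err^2)), 2)
})

test_that("ankle sign convention is dorsiflexion-positive", {
  n <- 150; fs <- 100
  t <- (0:(n - 1)) / fs
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  # plantarflexion: foot pitches forward/down relative to the shank,
  # i.e. foot inclination grows faster -> omega_y more negative
  foot <- imu_sequence(t, acc, matrix(rep(c(0, -0.5, 0), each = n), n, 3), fs = fs)
  shank <- imu_sequence(t, acc, matrix(0, n, 3), fs = fs)
  ank <- ankle_angle(foot, shank)
  expect_lt(ank[n], -0.5)
})

test_that("knee range of motion is offset-invariant max minus min", {
  iv <- cbind(1L, 101L)
  flat <- rep(0.3, 100)
  expect_equal(knee_rom(flat, iv), 0)
  series <- seq(7.2, 66.2, length.out = 100) * pi / 180
  expect_equal(knee_rom(series, iv), 59, tolerance = 1e-9)
  expect_equal(knee_rom(series + 0.5, iv), 59, tolerance = 1e-9)
})

test_that("gait parameters aggregate with exact mean/SD bookkeeping", {
  strides <- data.frame(
    start_ic = 0:8 * 1.32, end_ic = 1:9 * 1.32, cycle = 1.32,
    stance_time = 0.86, swing_time = 0.46, length = 1.21,
    speed = 1.21 / 1.32, clearance_max = 0.22)
  p <- compute_gait_parameters(strides, knee_rom_deg = rep(59, 9))
  expect_true(all(p$summary$sd == 0))
  expect_equal(p$summary$mean[p$summary$parameter == "stride_speed"],
               0.9167, tolerance = 1e-3)
  expect_equal(p$summary$mean[p$summary$parameter == "stride_frequency"],
               120 / 1.32, tolerance = 1e-9)
  # brute-force mean/SD agreement on jittered strides
  set.seed(34)
  strides$length <- strides$length + stats::rnorm(9, sd = 0.02)
  p2 <- compute_gait_parameters(strides, drop_outliers = FALSE)
  expect_equal(p2$summary$mean[p2$summary$parameter == "stride_length"],
               mean(strides$length), tolerance = 1e-12)
  expect_equal(p2$summary$sd[p2$summary$parameter == "stride_length"],
               stats::sd(strides$length), tolerance = 1e-12)
})
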