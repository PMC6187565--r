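test_that("gravity error is the cross product with the predicted direction", {
  q <- quat_identity()
  expect_equal(gravity_error(c(0, 0, 9.81), q), c(0, 0, 0))
  expect_equal(gravity_error(c(0, 1, 0), q), c(1, 0, 0))
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(3)
    ang <- acos(min(1, max(-1, a[3] / sqrt(sum(a^2)))))
    expect_equal(sqrt(sum(gravity_error(a, q)^2)), sin(ang),
                 tolerance = 1e-12)
  }
  expect_error(gravity_error(c(0, 0, 0), q), "zero-norm")
})

test_that("magnetic error corrects heading only", {
  B <- c(22, 0, -40)
  # attitude consistent with the measurement: no correction
  expect_lt(max(abs(magnetic_error(B, quat_identity()))), 1e-12)
  # pure 10-degree heading offset: error along the vertical axis with
  # magnitude sin(10 deg) scaled by the horizontal field fraction
  psi <- 10 * pi / 180
  q_est <- euler_to_quat(0, 0, 0)
  m_meas <- rotate_vector(quat_conjugate(euler_to_quat(0, 0, psi)), B)
  e <- magnetic_error(m_meas, q_est)
  expect_lt(max(abs(e[1:2])), 1e-6)
  hh2 <- (22 / sqrt(sum(B^2)))^2
  expect_equal(abs(e[3]), sin(psi) * hh2, tolerance = 1e-6)
  # vertical field: declared degenerate, zero correction with warning
  expect_warning(ez <- magnetic_error(c(0, 0, -40), quat_identity()),
                 "vertical")
  expect_equal(ez, c(0, 0, 0))
})

test_that("PI correction applies proportional and integral action", {
  cfg <- fusion_config(kp = 2, ki = 0, tau = 0.01)
  st <- fusion_state()
  out <- pi_correct(c(0, 0, 0), c(0.1, 0, 0), st, cfg)
  expect_equal(out$omega, c(0.2, 0, 0))
  # zero error leaves rate and accumulator untouched
  out0 <- pi_correct(c(0.5, -0.2, 0.1), c(0, 0, 0), st, cfg)
  expect_equal(out0$omega, c(0.5, -0.2, 0.1))
  expect_equal(out0$state$integral, st$integral)
  # constant error with ki > 0: correction grows linearly across calls
  cfg2 <- fusion_config(kp = 0, ki = 1, tau = 0.5)
  st <- fusion_state()
  outs <- numeric(4)
  for (k in 1:4) {
    res <- pi_correct(c(0, 0, 0), c(0.2, 0, 0), st, cfg2)
    st <- res$state
    outs[k] <- res$omega[1]
  }
  expect_equal(outs, 0.1 * (1:4))
})

test_that("fusion holds a stationary attitude and converges from tilt", {
  s <- noiseless_session(n_strides = 3)
  seq <- s$sequences$foot_L
  n_still <- round(1.5 * seq$fs)
  still <- imu_sequence(seq$t[1:n_still], seq$acc[1:n_still, ],
                        seq$gyro[1:n_still, ], seq$mag[1:n_still, ],
                        fs = seq$fs)
  q_true <- s$truth$segments$foot_L$quat[1, ]
  qs <- fuse_sequence(still, fusion_config(), q0 = q_true)
  expect_lt(max(abs(qs - matrix(q_true, n_still, 4, byrow = TRUE))), 1e-6)
  # 10-degree initial tilt decays below 0.5 degrees within 5 s
  longer <- imu_sequence(seq(0, 6, by = 0.01),
                         matrix(rep(c(0, 0, 9.81), each = 601), 601, 3),
                         matrix(0, 601, 3), fs = 100)
  q0 <- quat_multiply(quat_identity(),
                      quat_from_axis_angle(c(1, 0, 0), 10 * pi / 180))
  qs2 <- fuse_sequence(longer, fusion_config(use_mag = FALSE), q0 = q0)
  err5 <- quat_angle_between(qs2[501, ], quat_identity()) * 180 / pi
  expect_lt(err5, 0.5)
})

test_that("all fused quaternions stay unit norm", {
  s <- default_session(n_strides = 5, noise_seed = 7)
  qs <- fuse_sequence(s$sequences$foot_R)
  expect_lt(max(abs(sqrt(rowSums(qs^2)) - 1)), 1e-9)
})

test_that("zero gains reduce fusion to open-loop rate integration", {
  s <- default_session(n_strides = 4, noise_seed = 8)
  seq <- s$sequences$foot_L
  q0 <- initial_attitude(seq)
  got <- fuse_sequence(seq, fusion_config(kp = 0, ki = 0), q0 = q0)
  # reference: direct propagation with the same midpoint rates
  want <- matrix(NA_real_, nrow(got), 4)
  want[1, ] <- q <- quat_normalize(q0)
  for (i in 2:nrow(got)) {
    w <- 0.5 * (seq$gyro[i - 1, ] + seq$gyro[i, ])
    q <- quat_propagate(q, w, seq$t[i] - seq$t[i - 1])
    want[i, ] <- q
  }
  expect_identical(got, want)
})

test_that("feedback bounds attitude error under sustained gyro bias", {
  n <- 3000; fs <- 100
  t <- (0:(n - 1)) / fs
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  gyro <- matrix(rep(c(0.01, 0, 0), each = n), n, 3)  # 0.01 rad/s roll bias
  seq <- imu_sequence(t, acc, gyro, fs = fs)
  fused <- fuse_sequence(seq, fusion_config(use_mag = FALSE),
                         q0 = quat_identity())
  open <- fuse_sequence(seq, fusion_config(kp = 0, ki = 0),
                        q0 = quat_identity())
  err_f <- quat_angle_between(fused[n, ], quat_identity()) * 180 / pi
  err_o <- quat_angle_between(open[n, ], quat_identity()) * 180 / pi
  expect_lt(err_f, 2)
  expect_gt(err_o, 10)   # 0.01 rad/s over 30 s ~ 17 degrees, unbounded
})

test_that("fusion beats open-loop integration on simulated gait", {
  s <- default_session(n_strides = 12, noise_seed = 9)
  seq <- s$sequences$foot_L
  truth_q <- s$truth$segments$foot_L$quat
  q0 <- s$truth$segments$foot_L$quat[1, ]
  mask <- detect_stance(seq)
  fused <- fuse_sequence(seq, fusion_config(), q0 = q0,
                         static_mask = mask$mask == 1)
  open <- fuse_sequence(seq, fusion_config(kp = 0, ki = 0), q0 = q0)
  ang_errs <- function(qs) {
    vapply(seq_len(nrow(qs)),
           function(i) quat_angle_between(qs[i, ], truth_q[i, ]),
           numeric(1))
  }
  expect_lt(sqrt(mean(ang_errs(fused)^2)), sqrt(mean(ang_errs(open)^2)))
})

test_that("heading-only offsets never disturb the gravity direction", {
  B <- c(22, 0, -40)
  set.seed(32)
  for (i in 1:10) {
    psi <- stats::runif(1, -pi / 4, pi / 4)
    q_est <- quat_identity()
    m_meas <- rotate_vector(quat_conjugate(euler_to_quat(0, 0, psi)), B)
    e <- magnetic_error(m_meas, q_est)
    # the correction leaves the estimated gravity direction untouched:
    # its horizontal (roll/pitch-acting) components vanish
    expect_lt(sqrt(sum(e[1:2]^2)), 1e-6)
  }
})

test_that("timestamp gaps are reported as errors", {
  t <- c(seq(0, 0.5, by = 0.01), seq(0.8, 1.2, by = 0.01))
  n <- length(t)
  seq <- imu_sequence(t, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                      matrix(0, n, 3), fs = 100)
  expect_error(fuse_sequence(seq), "gap")
})

test_that("initial attitude recovers the simulator's standing pose", {
  s <- default_session(n_strides = 3, noise_seed = 10)
  angles <- estimate_nonortho_angles(fit_ellipsoid(s$calibration$accel_cloud))
  cal <- calibrate_magnetometer(s$calibration$mag_sweep)
  for (nm in c("foot_L", "thigh_R", "shank_L")) {
    seq <- s$sequences[[nm]]
    seq$acc <- correct_accel(seq$acc, angles, exact = TRUE)
    seq$mag <- apply_mag_calibration(seq$mag, cal)
    q0 <- initial_attitude(seq)
    q_true <- s$truth$segments[[nm]]$quat[1, ]
    expect_lt(quat_angle_between(q0, q_true) * 180 / pi, 0.5)
  }
})
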