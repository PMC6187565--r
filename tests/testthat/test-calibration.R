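test_that("ellipsoid fit recovers spheres and ellipsoids exactly", {
  # sphere: degenerate equal-radii case
  pts <- ellipsoid_points(50, c(1, 1, 1), seed = 1)
  f <- fit_ellipsoid(pts)
  co <- f$coeffs
  expect_lt(abs(co["a"] - co["b"]), 1e-8)
  expect_lt(abs(co["b"] - co["c"]), 1e-8)
  expect_lt(max(abs(co[c("f", "g", "h")])), 1e-8)
  expect_lt(max(abs(f$center)), 1e-8)
  expect_lt(max(abs(f$radii - 1)), 1e-8)
  # axis-aligned ellipsoid with offset center
  pts <- ellipsoid_points(120, c(1, 2, 3), center = c(0.1, -0.2, 0.3), seed = 2)
  f <- fit_ellipsoid(pts)
  expect_lt(max(abs(f$center - c(0.1, -0.2, 0.3))), 1e-6)
  expect_lt(max(abs(sort(f$radii) - c(1, 2, 3))), 1e-6)
})

test_that("fitted coefficients satisfy the unit ellipsoid constraint", {
  M <- ellipsoid_M_full()
  for (seed in 1:5) {
    pts <- ellipsoid_points(80, c(0.8, 1.1, 1.4), center = c(0.2, 0, -0.1),
                            seed = seed)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = 0.003), ncol = 3)
    O <- fit_ellipsoid(pts)$coeffs
    expect_lt(abs(drop(t(O) %*% M %*% O) - 1), 1e-9)
  }
})

test_that("geometry extraction undoes a known rotation", {
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  pts <- ellipsoid_points(150, c(1, 2, 3), center = c(0.3, 0.1, -0.2),
                          rot = rot, seed = 3)
  f <- fit_ellipsoid(pts)
  expect_lt(max(abs(sort(f$radii) - c(1, 2, 3))), 1e-6)
  # translating and rotating the points onto principal axes gives the
  # standard form x^2/a'^2 + y^2/b'^2 + z^2/c'^2 = 1
  y <- sweep(pts, 2, f$center) %*% f$axes
  resid <- rowSums(sweep(y, 2, f$radii, "/")^2) - 1
  expect_lt(max(abs(resid)), 1e-6)
  # recovered axes match the construction up to sign/permutation
  match_mat <- abs(t(f$axes) %*% rot)
  expect_true(all(apply(match_mat, 1, max) > 1 - 1e-6))
})

test_that("degenerate point clouds are rejected with a fit error", {
  expect_error(fit_ellipsoid(matrix(stats::rnorm(15), ncol = 3)), "10 points")
  flat <- cbind(stats::rnorm(40), stats::rnorm(40), 0)  # coplanar
  expect_error(fit_ellipsoid(flat), "degenerate|ellipsoid")
})

test_that("non-orthogonality angles are recovered from static clouds", {
  # perfect sensor: all angles vanish
  pts <- ellipsoid_points(200, rep(9.81, 3), seed = 4)
  ang <- estimate_nonortho_angles(fit_ellipsoid(pts))
  expect_lt(max(abs(c(ang$alpha, ang$beta, ang$gamma))), 1e-9)
  # injected angles, noiseless forward model at 200 random orientations
  truth <- nonortho_angles(0.5 * pi / 180, 0.3 * pi / 180, 0.8 * pi / 180)
  E <- nonortho_matrix(truth)
  set.seed(5)
  dirs <- matrix(stats::rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  est <- estimate_nonortho_angles(fit_ellipsoid((9.81 * dirs) %*% t(E)))
  err_deg <- abs(c(est$alpha - truth$alpha, est$beta - truth$beta,
                   est$gamma - truth$gamma)) * 180 / pi
  expect_lt(max(err_deg), 0.02)
})

test_that("angle recovery degrades gracefully with sensor noise", {
  truth <- c(0.5, 0.3, 0.8) * pi / 180
  errs <- sapply(1:20, function(seed) {
    cloud <- static_orientation_cloud(
      sensor_error_model(seed = seed), n_orient = 40, n_per = 10)
    est <- estimate_nonortho_angles(fit_ellipsoid(cloud))
    max(abs(c(est$alpha, est$beta, est$gamma) - truth)) * 180 / pi
  })
  expect_lt(max(errs), 0.1)
})

test_that("angle-estimation error grows monotonically with noise", {
  rmse_at <- function(sd_noise) {
    errs <- sapply(1:8, function(seed) {
      err <- sensor_error_model(accel_noise_sd = sd_noise, seed = seed)
      cloud <- static_orientation_cloud(err, n_orient = 40, n_per = 10)
      est <- estimate_nonortho_angles(fit_ellipsoid(cloud))
      truth <- c(0.5, 0.3, 0.8) * pi / 180
      sqrt(mean((c(est$alpha, est$beta, est$gamma) - truth)^2))
    })
    sqrt(mean(errs^2))
  }
  r <- c(rmse_at(0), rmse_at(0.01), rmse_at(0.05))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("accelerometer correction inverts the misalignment model", {
  angles <- nonortho_angles(0.5 * pi / 180, 0.3 * pi / 180, 0.8 * pi / 180)
  none <- nonortho_angles(0, 0, 0)
  v <- c(3, -5, 7)
  expect_equal(correct_accel(v, none), v)
  E <- nonortho_matrix(angles)
  set.seed(6)
  for (i in 1:20) {
    v <- stats::rnorm(3, sd = 5)
    # small-angle inverse: second-order residual
    got <- correct_accel(drop(E %*% v), angles)
    expect_lt(sqrt(sum((got - v)^2)), 2e-4 * sqrt(sum(v^2)))
    # exact inverse: machine precision
    got2 <- correct_accel(drop(E %*% v), angles, exact = TRUE)
    expect_lt(sqrt(sum((got2 - v)^2)), 1e-12 * sqrt(sum(v^2)))
  }
})

test_that("correction tightens stationary norms toward gravity", {
  angles <- nonortho_angles(0.5 * pi / 180, 0.3 * pi / 180, 0.8 * pi / 180)
  E <- nonortho_matrix(angles)
  set.seed(7)
  dirs <- matrix(stats::rnorm(900), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  raw <- (9.81 * dirs) %*% t(E)
  corrected <- correct_accel(raw, angles)
  var_raw <- stats::var(sqrt(rowSums(raw^2)))
  var_cor <- stats::var(sqrt(rowSums(corrected^2)))
  expect_lt(var_cor, var_raw)
})

test_that("magnetometer calibration recovers hard and soft iron", {
  # undistorted field: identity calibration
  cal0 <- calibrate_magnetometer(figure_eight_sweep(ideal_sensor_model(),
                                                    n = 800))
  expect_lt(max(abs(cal0$offset)), 1e-6)
  expect_lt(max(abs(cal0$matrix - diag(3))), 1e-6)
  # hard iron (10,-5,3) and diagonal soft iron, noiseless
  err <- sensor_error_model(mag_noise_sd = 0, seed = 8)
  cal <- calibrate_magnetometer(figure_eight_sweep(err, n = 800))
  expect_lt(max(abs(cal$offset - c(10, -5, 3))), 0.01)
  want <- diag(1 / c(1.1, 0.9, 1.0))
  expect_lt(max(abs(cal$matrix - want) / diag(want)), 0.01)
  # calibrated samples sit on a sphere: CV below 0.5 %
  sw <- figure_eight_sweep(err, n = 800)
  norms <- sqrt(rowSums(apply_mag_calibration(sw, cal)^2))
  expect_lt(stats::sd(norms) / mean(norms), 0.005)
})

test_that("applying a calibration is the documented affine map", {
  ident <- structure(list(offset = c(0, 0, 0), matrix = diag(3)),
                     class = "mag_calibration")
  expect_equal(apply_mag_calibration(c(1, 2, 3), ident), c(1, 2, 3))
  off <- structure(list(offset = c(4, -1, 2), matrix = diag(3)),
                   class = "mag_calibration")
  expect_equal(apply_mag_calibration(c(4, -1, 2), off), c(0, 0, 0))
  # noiseless distorted round trip: direction exact, magnitude to the
  # mean-norm convention (soft iron absorbs absolute scale)
  err <- sensor_error_model(mag_noise_sd = 0, seed = 9)
  cal <- calibrate_magnetometer(figure_eight_sweep(err, n = 800))
  B <- c(22, 0, -40)
  raw <- drop(err$soft_iron %*% B) + err$hard_iron
  got <- apply_mag_calibration(raw, cal)
  cosang <- sum(got * B) / sqrt(sum(got^2) * sum(B^2))
  expect_lt(abs(cosang - 1), 1e-9)
  expect_lt(abs(sqrt(sum(got^2)) / sqrt(sum(B^2)) - 1), 0.01)
})

test_that("calibration configs survive a write/read round trip", {
  angles <- nonortho_angles(0.004, -0.002, 0.009)
  err <- sensor_error_model(mag_noise_sd = 0, seed = 10)
  mag <- calibrate_magnetometer(figure_eight_sweep(err, n = 800))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(path, angles = angles, mag = mag)
  back <- read_calibration(path)
  expect_equal(back$nonortho$alpha, angles$alpha, tolerance = 1e-12)
  expect_equal(back$mag$offset, mag$offset, tolerance = 1e-9)
  expect_equal(back$mag$matrix, mag$matrix, tolerance = 1e-9)
})
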