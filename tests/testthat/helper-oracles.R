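# Independent oracles used across the suite.  These deliberately use
# different constructions from the package implementation.

# rotation matrix from a quaternion via the outer-product/skew identity
# R = (q0^2 - |v|^2) I + 2 v v' + 2 q0 [v]x
oracle_quat_matrix <- function(q) {
  q0 <- q[1]; v <- q[2:4]
  skew <- matrix(c(0, -v[3], v[2],
                   v[3], 0, -v[1],
                   -v[2], v[1], 0), 3, 3, byrow = TRUE)
  (q0^2 - sum(v^2)) * diag(3) + 2 * tcrossprod(v) + 2 * q0 * skew
}

# Z-Y-X Euler decomposition straight from rotation-matrix entries
oracle_euler_from_matrix <- function(R) {
  list(phi = atan2(R[3, 2], R[3, 3]),
       theta = -asin(max(-1, min(1, R[3, 1]))),
       psi = atan2(R[2, 1], R[1, 1]))
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

quat_angle_between <- function(qa, qb) {
  # chord-based rotation angle: |qa -/+ qb| = 2 sin(theta/4); exact near 0
  # where the acos of the dot product loses half the mantissa
  d <- min(sqrt(sum((qa - qb)^2)), sqrt(sum((qa + qb)^2)))
  4 * asin(min(1, d / 2))
}

# brute-force trailing-window statistics
oracle_moving_variance <- function(x, N) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (j in N:n) {
    w <- x[(j - N + 1):j]
    out[j] <- mean((w - mean(w))^2)
  }
  out
}

oracle_gyro_energy <- function(g, W, s2) {
  n <- nrow(g)
  out <- rep(NA_real_, n)
  for (j in W:n) out[j] <- sum(g[(j - W + 1):j, ]^2) / (s2 * W)
  out
}

# exact points on an ellipsoid: center + R diag(radii) * unit directions
ellipsoid_points <- function(n, radii, center = c(0, 0, 0), rot = diag(3),
                             seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u %*% diag(radii) %*% t(rot), 2, center, "+")
}

# small standard sessions shared by several tests
default_session <- function(n_strides = 10, sim_seed = 1, noise_seed = 1) {
  simulate_session(gait_config(n_strides = n_strides, seed = sim_seed),
                   sensor_error_model(seed = noise_seed))
}

noiseless_session <- function(n_strides = 8, sim_seed = 1) {
  simulate_session(gait_config(n_strides = n_strides, seed = sim_seed),
                   ideal_sensor_model())
}

# full constraint matrix M of the ellipsoid fit (quadratic block M0, zero
# padded), for checking O' M O = 1
ellipsoid_M_full <- function() {
  M0 <- diag(c(-1, -1, -1, -4, -4, -4))
  M0[1, 2] <- M0[2, 1] <- 1
  M0[1, 3] <- M0[3, 1] <- 1
  M0[2, 3] <- M0[3, 2] <- 1
  M <- matrix(0, 10, 10)
  M[1:6, 1:6] <- M0
  M
}
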