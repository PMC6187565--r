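# Sensor calibration by constrained ellipsoid fitting.
#
# A triad with small inter-axis misalignment distorts the spherical locus of
# constant-magnitude reference vectors (gravity for the accelerometer, the
# geomagnetic field for the magnetometer) into an ellipsoid.  Fitting that
# ellipsoid under the 4B - A^2 > 0 ellipsoid constraint recovers the
# distortion analytically.

#' Small non-orthogonality angles of an accelerometer triad
#'
#' The misalignment is modeled by the unit-diagonal small-angle matrix
#' `E = [[1, 0, alpha], [beta, 1, gamma], [0, 0, 1]]` mapping true specific
#' force to the measured one.
#'
#' @param alpha,beta,gamma misalignment angles in radians; each must satisfy
#'   `|angle| < 0.1` (small-angle validity).
#' @return object of class `nonortho_angles`.
#' @export
nonortho_angles <- function(alpha = 0, beta = 0, gamma = 0) {
  a <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(a))) stopf("angles must be finite")
  if (any(abs(a) >= 0.1))
    stopf("non-orthogonality angles must satisfy |angle| < 0.1 rad")
  structure(as.list(a), class = "nonortho_angles")
}

#' @export
print.nonortho_angles <- function(x, ...) {
  cat(sprintf("non-orthogonality angles (deg): alpha = %.4f, beta = %.4f, gamma = %.4f\n",
              rad2deg(x$alpha), rad2deg(x$beta), rad2deg(x$gamma)))
  invisible(x)
}

#' Forward misalignment matrix
#'
#' Exact trigonometric form of the triad misalignment:
#' rows `(cos a, 0, sin a)`, `(sin b cos g, cos b cos g, sin g)`, `(0, 0, 1)`.
#' Used by the simulator as the forward distortion model; reduces to the
#' small-angle matrix for small angles.
#'
#' @param angles a [nonortho_angles()] object.
#' @return 3 x 3 matrix.
#' @export
nonortho_matrix <- function(angles) {
  a <- angles$alpha; b <- angles$beta; g <- angles$gamma
  matrix(c(cos(a),            0,                 sin(a),
           sin(b) * cos(g),   cos(b) * cos(g),   sin(g),
           0,                 0,                 1),
         nrow = 3L, byrow = TRUE)
}

# Ellipsoid-condition matrix for the constrained fit: O' M O = 4B - A^2 for
# the quadratic-part coefficients, zero-padded over the linear coefficients.
.ellipsoid_M0 <- function() {
  M0 <- diag(c(-1, -1, -1, -4, -4, -4))
  M0[1L, 2L] <- M0[2L, 1L] <- 1
  M0[1L, 3L] <- M0[3L, 1L] <- 1
  M0[2L, 3L] <- M0[3L, 2L] <- 1
  M0
}

#' Fit an ellipsoid to a 3-D point cloud under the ellipsoid constraint
#'
#' Fits the quadric `a x^2 + b y^2 + c z^2 + 2f yz + 2g xz + 2h xy + 2p x +
#' 2q y + 2r z + d = 0` by minimizing the algebraic residual `||C O||^2`
#' subject to `O' M O = 1`, where the constraint fixes `4B - A^2 = 1` with
#' `A = a + b + c`, `B = ab + bc + ac - f^2 - g^2 - h^2`; this guarantees the
#' solution is an ellipsoid.  The constrained problem is solved as the
#' generalized eigenproblem `C'C O = lambda M O` (reduced to the quadratic
#' block, since `M` is singular); among the admissible eigenvectors the one
#' with the smallest algebraic residual is returned, with the sign normalized
#' so that `a + b + c > 0`.
#'
#' @param points n x 3 matrix of points on (or near) the surface, n >= 10 and
#'   non-coplanar.
#' @return object of class `ellipsoid_model` with elements `coeffs` (named
#'   vector `a..d`), `S` (symmetric quadratic-form matrix), `Tvec`
#'   (`c(2p, 2q, 2r)`), `center`, `radii`, `axes` (orthonormal columns),
#'   `evals` (eigenvalues of `S`), and `k` (right-hand side of the centered
#'   form `y' S y = k`).
#' @export
fit_ellipsoid <- function(points) {
  pts <- as_matrix3(points, "points")
  n <- nrow(pts)
  if (n < 10L) stopf("ellipsoid fit needs at least 10 points, got %d", n)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  C <- cbind(x^2, y^2, z^2, 2 * y * z, 2 * x * z, 2 * x * y,
             2 * x, 2 * y, 2 * z, 1)
  G <- crossprod(C)
  S11 <- G[1:6, 1:6]; S12 <- G[1:6, 7:10]; S22 <- G[7:10, 7:10]
  if (rcond(S22) < 1e-14)
    stopf("degenerate point cloud: linear normal-equation block is singular")
  Sred <- S11 - S12 %*% solve(S22, t(S12))
  M0 <- .ellipsoid_M0()
  eg <- eigen(solve(M0, Sred))
  # Candidate eigenvectors are normalized to |O' M O| = 1.  The constraint
  # sign equals the sign of 4B - A^2, which is positive only for mildly
  # eccentric ellipsoids (axis ratios below ~2); strongly elongated
  # ellipsoids live on the -1 branch of the same pencil, so both branches
  # are searched and each candidate is kept only if its quadric really is
  # an ellipsoid (positive-definite form with a positive centered radius).
  best <- NULL
  for (j in seq_len(6L)) {
    if (abs(Im(eg$values[j])) > 1e-8 * max(1, abs(Re(eg$values[j])))) next
    O1 <- Re(eg$vectors[, j])
    kappa <- drop(t(O1) %*% M0 %*% O1)
    if (abs(kappa) <= 1e-12 * sum(O1^2)) next
    O1 <- O1 / sqrt(abs(kappa))
    O2 <- drop(-solve(S22, t(S12) %*% O1))
    O <- c(O1, O2)
    if (sum(O[1:3]) < 0) O <- -O
    S <- matrix(c(O[1], O[6], O[5],
                  O[6], O[2], O[4],
                  O[5], O[4], O[3]), 3L, 3L)
    ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) rep(-1, 3))
    if (any(ev <= 0)) next
    tvec <- O[7:9]
    k <- drop(t(tvec) %*% solve(S, tvec)) - O[10]
    if (!is.finite(k) || k <= 0) next
    resid <- drop(t(O) %*% G %*% O)
    if (is.null(best) || resid < best$resid) best <- list(O = O, resid = resid)
  }
  if (is.null(best))
    stopf(paste0("ellipsoid fit failed: no eigenvector of the constrained ",
                 "pencil yields an ellipsoid (point cloud degenerate or ",
                 "not ellipsoidal)"))
  O <- best$O
  names(O) <- c("a", "b", "c", "f", "g", "h", "p", "q", "r", "d")
  model <- structure(
    list(coeffs = O,
         S = matrix(c(O["a"], O["h"], O["g"],
                      O["h"], O["b"], O["f"],
                      O["g"], O["f"], O["c"]), 3L, 3L,
                    dimnames = NULL),
         Tvec = unname(2 * O[c("p", "q", "r")]),
         n = n, residual = best$resid),
    class = "ellipsoid_model")
  geom <- ellipsoid_geometry(model)
  model$center <- geom$center
  model$radii <- geom$radii
  model$axes <- geom$axes
  model$evals <- geom$evals
  model$k <- geom$k
  model
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat("ellipsoid fit:", x$n, "points\n")
  cat(sprintf("  center: (%.4g, %.4g, %.4g)\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  radii : (%.4g, %.4g, %.4g)\n",
              x$radii[1], x$radii[2], x$radii[3]))
  invisible(x)
}

#' Center, radii and principal axes of a fitted ellipsoid
#'
#' The center is the stationary point of the quadric, `-S^{-1} (p, q, r)`;
#' translating there reduces the quadric to `y' S y = k` whose
#' eigendecomposition `S = N D N'` yields semi-axes `sqrt(k / D_ii)` along the
#' eigenvector directions.  Axes are permuted/signed to the assignment closest
#' to the identity (misalignment angles are small, so the fitted frame is a
#' small perturbation of the sensor frame).
#'
#' @param model an `ellipsoid_model` (only `coeffs`/`S`/`Tvec` are used).
#' @return list with `center`, `radii`, `axes`, `evals`, `k`.
#' @export
ellipsoid_geometry <- function(model) {
  S <- model$S
  tvec <- model$Tvec / 2
  d <- unname(model$coeffs["d"])
  if (rcond(S) < 1e-14) stopf("ellipsoid geometry failed: singular form matrix")
  center <- drop(-solve(S, tvec))
  k <- drop(t(tvec) %*% solve(S, tvec)) - d
  eg <- eigen(S, symmetric = TRUE)
  if (any(eg$values <= 0) || k <= 0)
    stopf("ellipsoid geometry failed: quadric is not an ellipsoid")
  # closest-to-identity column assignment (greedy on |axes|)
  N <- eg$vectors
  vals <- eg$values
  perm <- integer(3L)
  used <- logical(3L)
  for (i in 1:3) {
    cand <- which(!used)
    perm[i] <- cand[which.max(abs(N[i, cand]))]
    used[perm[i]] <- TRUE
  }
  N <- N[, perm, drop = FALSE]
  vals <- vals[perm]
  for (i in 1:3) if (N[i, i] < 0) N[, i] <- -N[, i]
  list(center = center,
       radii = sqrt(k / vals),
       axes = N,
       evals = vals,
       k = k)
}

#' Estimate accelerometer non-orthogonality angles from a static fit
#'
#' Multi-orientation static accelerometer readings lie on the ellipsoid
#' `x' Q x = 1` with `Q = E^{-T} E^{-1} / g^2`, so `P = (g^2 Q)^{-1} = E E'`.
#' With the misalignment sparsity of [nonortho_matrix()], `P` factors
#' analytically: after normalizing `P` by `P[3,3]` (which removes any overall
#' scale, making the estimate independent of the assumed gravity magnitude),
#' `alpha = asin(P13)`, `gamma = asin(P23)` and
#' `sin(beta) = (P12 - sin(alpha) sin(gamma)) / (cos(alpha) cos(gamma))`.
#'
#' @param model ellipsoid model fitted to static multi-orientation
#'   accelerometer data (units m/s^2).
#' @param g_mag local gravity magnitude (m/s^2), used only to sanity-check the
#'   fitted scale.
#' @return a [nonortho_angles()] object.
#' @export
estimate_nonortho_angles <- function(model, g_mag = STANDARD_GRAVITY) {
  Q <- model$S / model$k
  P <- solve(Q) / g_mag^2
  mean_radius <- exp(mean(log(model$radii)))
  if (abs(mean_radius - g_mag) / g_mag > 0.2)
    warnf("fitted mean radius %.3f differs from gravity %.3f by > 20%% - check units",
          mean_radius, g_mag)
  P <- P / P[3L, 3L]
  sa <- clamp(P[1L, 3L], -1, 1)
  sg <- clamp(P[2L, 3L], -1, 1)
  alpha <- asin(sa)
  gamma <- asin(sg)
  sb <- clamp((P[1L, 2L] - sa * sg) / (cos(alpha) * cos(gamma)), -1, 1)
  beta <- asin(sb)
  if (any(abs(c(alpha, beta, gamma)) >= 0.1))
    stopf(paste0("estimated angles exceed the 0.1 rad small-angle model ",
                 "(alpha = %.4f, beta = %.4f, gamma = %.4f rad)"),
          alpha, beta, gamma)
  nonortho_angles(alpha, beta, gamma)
}

#' Correct accelerometer readings for non-orthogonality
#'
#' Applies the small-angle inverse
#' `E^{-1} = [[1, 0, -alpha], [-beta, 1, alpha*beta - gamma], [0, 0, 1]]`
#' to raw readings; the residual after a forward-model round trip is second
#' order in the angles.
#'
#' @param raw 3-vector or n x 3 matrix of raw accelerometer samples (m/s^2).
#' @param angles a [nonortho_angles()] object.
#' @param exact invert the full trigonometric misalignment matrix
#'   ([nonortho_matrix()]) instead of the small-angle inverse.  The
#'   small-angle form leaves a second-order residual (~2e-4 of the signal)
#'   which is negligible at rest but, applied to swing-phase accelerations
#'   of tens of m/s^2, integrates into a visible per-stride position bias;
#'   the pipeline therefore uses the exact inverse.
#' @return corrected samples, same shape as `raw`.
#' @export
correct_accel <- function(raw, angles, exact = FALSE) {
  if (exact) {
    Einv <- solve(nonortho_matrix(angles))
  } else {
    a <- angles$alpha; b <- angles$beta; g <- angles$gamma
    Einv <- matrix(c(1,  0, -a,
                     -b, 1, a * b - g,
                     0,  0, 1), nrow = 3L, byrow = TRUE)
  }
  vec <- is.null(dim(raw))
  m <- as_matrix3(raw, "raw") %*% t(Einv)
  if (vec) drop(m) else m
}

#' Magnetometer hard/soft-iron calibration from a figure-eight sweep
#'
#' Fits an ellipsoid to the sweep: the hard-iron offset is the fitted center
#' and the soft-iron correction is the symmetric positive-definite matrix
#' square root of the centered form matrix, scaled so calibrated samples have
#' norm equal to the mean field magnitude `mean(||m - offset||)`.
#'
#' @param points n x 3 matrix of raw magnetometer samples covering at least a
#'   hemisphere of orientations.
#' @return object of class `mag_calibration` with `offset` (3-vector),
#'   `matrix` (3 x 3 symmetric positive-definite) and `field` (scalar field
#'   magnitude).
#' @export
calibrate_magnetometer <- function(points) {
  pts <- as_matrix3(points, "points")
  fit <- fit_ellipsoid(pts)
  centered <- sweep(pts, 2L, fit$center)
  norms <- sqrt(rowSums(centered^2))
  units <- centered / norms
  cov_ev <- eigen(crossprod(units) / nrow(units), symmetric = TRUE,
                  only.values = TRUE)$values
  if (min(cov_ev) < 0.02)
    stopf("insufficient orientation coverage for magnetometer calibration")
  Q <- fit$S / fit$k
  eg <- eigen(Q, symmetric = TRUE)
  W0 <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  B <- mean(norms)
  structure(list(offset = fit$center, matrix = B * W0, field = B),
            class = "mag_calibration")
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat(sprintf("magnetometer calibration: field %.4g, offset (%.4g, %.4g, %.4g)\n",
              x$field, x$offset[1], x$offset[2], x$offset[3]))
  invisible(x)
}

#' Apply a magnetometer calibration
#'
#' @param raw 3-vector or n x 3 matrix of raw magnetometer samples.
#' @param cal a [calibrate_magnetometer()] result; an identity calibration can
#'   be built as `structure(list(offset = c(0,0,0), matrix = diag(3)), class =
#'   "mag_calibration")`.
#' @return `cal$matrix %*% (raw - cal$offset)`, same shape as `raw`.
#' @export
apply_mag_calibration <- function(raw, cal) {
  vec <- is.null(dim(raw))
  m <- sweep(as_matrix3(raw, "raw"), 2L, cal$offset) %*% t(cal$matrix)
  if (vec) drop(m) else m
}

#' Write calibration results to a plain-text (JSON) config file
#'
#' Keys: `nonortho` (alpha/beta/gamma, rad), `mag` (offset, matrix row-major,
#' field).  All values SI.
#'
#' @param path output file.
#' @param angles optional [nonortho_angles()].
#' @param mag optional [calibrate_magnetometer()] result.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(path, angles = NULL, mag = NULL) {
  out <- list()
  if (!is.null(angles))
    out$nonortho <- list(alpha = angles$alpha, beta = angles$beta,
                         gamma = angles$gamma)
  if (!is.null(mag))
    out$mag <- list(offset = mag$offset, matrix = as.vector(t(mag$matrix)),
                    field = mag$field)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration config written by [write_calibration()]
#' @param path config file.
#' @return list with elements `nonortho` and/or `mag`.
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(raw$nonortho))
    out$nonortho <- nonortho_angles(raw$nonortho$alpha, raw$nonortho$beta,
                                    raw$nonortho$gamma)
  if (!is.null(raw$mag))
    out$mag <- structure(list(offset = raw$mag$offset,
                              matrix = matrix(raw$mag$matrix, 3L, 3L,
                                              byrow = TRUE),
                              field = raw$mag$field),
                         class = "mag_calibration")
  out
}
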