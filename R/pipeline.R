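# End-to-end pipeline: calibrate -> correct -> fuse -> detect -> integrate
# -> segment -> parameters -> symmetry statistics.

#' Pipeline configuration
#'
#' @param stance a [stance_config()].
#' @param fusion a [fusion_config()].
#' @param g gravity magnitude (m/s^2).
#' @param t_bias_s duration of the initial standstill used for gyro-bias
#'   estimation and attitude initialization (s).
#' @param anova_strides number of leading steady-state strides per side
#'   entering the bilateral knee-ROM ANOVA (stride-paired groups).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stance = stance_config(),
                            fusion = fusion_config(),
                            g = STANDARD_GRAVITY, t_bias_s = 1,
                            anova_strides = 20L) {
  structure(list(stance = stance, fusion = fusion, g = g,
                 t_bias_s = t_bias_s,
                 anova_strides = as.integer(anova_strides)),
            class = "pipeline_config")
}

# constant per-axis gyro bias over the initial standstill
.estimate_gyro_bias <- function(seq, t_bias_s) {
  n0 <- max(3L, min(nrow(seq$gyro), round(t_bias_s * seq$fs)))
  colMeans(seq$gyro[seq_len(n0), , drop = FALSE])
}

.apply_sensor_calibration <- function(seq, angles, mag_cal, t_bias_s) {
  out <- seq
  if (!is.null(angles)) out$acc <- correct_accel(seq$acc, angles, exact = TRUE)
  if (!is.null(mag_cal) && !is.null(seq$mag))
    out$mag <- apply_mag_calibration(seq$mag, mag_cal)
  bias <- .estimate_gyro_bias(out, t_bias_s)
  out$gyro <- sweep(out$gyro, 2L, bias)
  attr(out, "gyro_bias") <- bias
  out
}

# full foot-track processing: fuse, stance, strapdown with ZVU, strides
.process_foot <- function(seq, cfg) {
  mask <- detect_stance(seq, cfg$stance, g = cfg$g)
  # refine the gyro bias over all stance samples (foot truly stationary),
  # shrinking the residual far below the one-second standstill estimate;
  # interval edges are eroded so detection-boundary samples with genuine
  # residual motion cannot contaminate the estimate
  iv <- mask$intervals
  stance_rows <- integer(0)
  for (r in seq_len(nrow(iv))) {
    gmax <- max(0L, (iv[r, "end"] - iv[r, "start"] - 3L) %/% 2L)
    gg <- min(5L, gmax)
    stance_rows <- c(stance_rows,
                     (iv[r, "start"] + gg):(iv[r, "end"] - 1L - gg))
  }
  if (length(stance_rows) >= 50L) {
    bias2 <- colMeans(seq$gyro[stance_rows, , drop = FALSE])
    seq$gyro <- sweep(seq$gyro, 2L, bias2)
  }
  quats <- fuse_sequence(seq, cfg$fusion, g = cfg$g,
                         static_mask = mask$mask == 1L)
  lin <- remove_gravity(seq$acc, quats, g = cfg$g)
  kin <- integrate_position_zvu(lin, mask, t = seq$t)
  strides <- segment_strides(mask, kin$position, t = seq$t)
  list(quats = quats, mask = mask, lin_acc = lin,
       velocity = kin$velocity, position = kin$position, strides = strides,
       t = seq$t)
}

#' Run the full gait-analysis pipeline on a session
#'
#' Stages: (1) accelerometer non-orthogonality calibration from the static
#' orientation cloud and magnetometer hard/soft-iron calibration from the
#' figure-eight sweep; (2) per-sensor correction and gyro-bias removal over
#' the initial standstill; (3) per-foot attitude fusion, stance detection
#' and ZVU-aided double integration; (4) stride segmentation and joint-angle
#' estimation (knee from thigh/shank, ankle from shank/foot, per-stride
#' drift resets at stance midpoints); (5) spatio-temporal parameters per
#' side and the stride-paired one-way ANOVA of bilateral knee ROM.
#'
#' @param session a [simulate_session()] result, or any list with the same
#'   `sequences` / `calibration` layout (e.g. read from disk).
#' @param cfg a [pipeline_config()].
#' @return object of class `gait_report`: list with `calibration` (angles,
#'   mag), `feet` (per-foot traces, masks, strides), `joints` (knee/ankle
#'   series), `parameters` (per-side [compute_gait_parameters()]), `anova`
#'   (bilateral knee ROM), `config`.
#' @export
run_pipeline <- function(session, cfg = pipeline_config()) {
  seqs <- session$sequences
  need_feet <- c("foot_L", "foot_R")
  if (!all(need_feet %in% names(seqs)))
    stopf("pipeline stage 'input': missing foot sequence(s) %s",
          paste(setdiff(need_feet, names(seqs)), collapse = ", "))
  angles <- NULL
  mag_cal <- NULL
  if (!is.null(session$calibration$accel_cloud)) {
    fit <- tryCatch(fit_ellipsoid(session$calibration$accel_cloud),
                    error = function(e) stopf("pipeline stage 'calibrate': %s",
                                              conditionMessage(e)))
    angles <- estimate_nonortho_angles(fit, g_mag = cfg$g)
  }
  if (!is.null(session$calibration$mag_sweep))
    mag_cal <- calibrate_magnetometer(session$calibration$mag_sweep)

  cal_seqs <- lapply(seqs, .apply_sensor_calibration, angles = angles,
                     mag_cal = mag_cal, t_bias_s = cfg$t_bias_s)

  feet <- list(foot_L = .process_foot(cal_seqs$foot_L, cfg),
               foot_R = .process_foot(cal_seqs$foot_R, cfg))

  joints <- list()
  parameters <- list()
  rom_per_side <- list()
  for (side in c("L", "R")) {
    foot_nm <- paste0("foot_", side)
    thigh_nm <- paste0("thigh_", side)
    shank_nm <- paste0("shank_", side)
    strides <- feet[[foot_nm]]$strides
    rom <- NULL
    if (all(c(thigh_nm, shank_nm) %in% names(cal_seqs))) {
      thigh <- cal_seqs[[thigh_nm]]
      shank <- cal_seqs[[shank_nm]]
      n0 <- max(3L, round(cfg$t_bias_s * thigh$fs))
      init <- list(
        theta_thigh0 = initial_segment_angle(
          thigh$acc[seq_len(n0), , drop = FALSE], g = cfg$g),
        theta_shank0 = initial_segment_angle(
          shank$acc[seq_len(n0), , drop = FALSE], g = cfg$g))
      # knee: drift reset at stance midpoints (knee sits at its stance
      # plateau there); ankle: no reset — the shank keeps moving with the
      # thigh during stance, so the ankle is nowhere near its standing
      # value at mid-stance and a reset would inject that offset
      knee <- knee_angle(thigh, shank, init,
                         stance = feet[[foot_nm]]$mask)
      ankle <- ankle_angle(cal_seqs[[foot_nm]], shank)
      joints[[paste0("knee_", side)]] <- knee
      joints[[paste0("ankle_", side)]] <- ankle
      if (nrow(strides) > 0L) rom <- knee_rom(knee, strides)
    }
    if (nrow(strides) > 0L)
      parameters[[side]] <- compute_gait_parameters(strides, rom)
    rom_per_side[[side]] <- if (is.null(rom)) numeric(0) else
      rom[rownames(strides) %in% rownames(parameters[[side]]$strides)]
  }

  anova <- NULL
  n_pair <- min(cfg$anova_strides, lengths(rom_per_side))
  if (n_pair >= 2L) {
    pairs <- lapply(seq_len(n_pair), function(i) {
      c(rom_per_side$L[i], rom_per_side$R[i])
    })
    anova <- tryCatch(one_way_anova(pairs), error = function(e) NULL)
  }

  structure(list(calibration = list(nonortho = angles, mag = mag_cal),
                 feet = feet, joints = joints, parameters = parameters,
                 anova = anova, config = cfg),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("gait report\n")
  for (side in names(x$parameters)) {
    cat(sprintf("-- side %s --\n", side))
    print(x$parameters[[side]])
  }
  if (!is.null(x$anova)) {
    cat("bilateral knee ROM ANOVA:\n")
    print(x$anova)
  }
  invisible(x)
}

#' Read a recorded session from a directory of delimited-text logs
#'
#' Expects `<segment>.csv` sensor logs (at least both feet) and optionally
#' `accel_cloud.csv` / `mag_sweep.csv` calibration captures, as written by
#' [write_session()].
#'
#' @param dir session directory.
#' @return a session list consumable by [run_pipeline()].
#' @export
read_session <- function(dir) {
  seqs <- list()
  for (nm in SEGMENT_LABELS) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) seqs[[nm]] <- read_imu_log(f, segment = nm)
  }
  if (length(seqs) == 0L) stopf("no sensor logs found in %s", dir)
  calib <- list()
  fa <- file.path(dir, "accel_cloud.csv")
  if (file.exists(fa)) calib$accel_cloud <- as.matrix(utils::read.csv(fa))
  fm <- file.path(dir, "mag_sweep.csv")
  if (file.exists(fm)) calib$mag_sweep <- as.matrix(utils::read.csv(fm))
  list(sequences = seqs, calibration = calib)
}

#' Write a gait report to a directory
#'
#' Emits per-stride CSVs (`strides_L.csv`, `strides_R.csv`), the mean/SD
#' summary (`summary.csv`), the bilateral knee-ROM ANOVA (`anova.csv`) and a
#' JSON report (`report.json`).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gait_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summaries <- list()
  for (side in names(report$parameters)) {
    p <- report$parameters[[side]]
    utils::write.csv(p$strides,
                     file.path(dir, sprintf("strides_%s.csv", side)),
                     row.names = FALSE, quote = FALSE)
    s <- p$summary
    s$side <- side
    summaries[[side]] <- s
  }
  if (length(summaries))
    utils::write.csv(do.call(rbind, summaries), file.path(dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$anova))
    write_anova_table(report$anova, file.path(dir, "anova.csv"))
  json <- list(
    parameters = lapply(report$parameters, function(p) {
      stats::setNames(as.list(p$summary$mean), p$summary$parameter)
    }),
    anova = if (!is.null(report$anova))
      report$anova[c("ss_columns", "df_columns", "ss_error", "df_error",
                     "f", "p")],
    calibration = if (!is.null(report$calibration$nonortho))
      report$calibration$nonortho[c("alpha", "beta", "gamma")])
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Position accuracy of the pipeline against simulator ground truth
#'
#' Runs the full pipeline on a simulated session and returns, per foot, the
#' RMS 3-D error between the estimated trajectory and the simulator's true
#' sensor displacement over the whole session.
#'
#' Following standard trajectory-evaluation practice for dead-reckoned
#' tracks compared against an external reference, the estimate's frame is
#' first registered to the truth frame by the single degree of freedom the
#' system cannot pin down better than its magnetometer calibration: one
#' least-squares rotation about gravity (`align_yaw = TRUE`).  Set
#' `align_yaw = FALSE` to score the raw, unregistered trajectories instead.
#'
#' @param session a [simulate_session()] result (must carry `truth`).
#' @param cfg a [pipeline_config()].
#' @param report optional precomputed [run_pipeline()] result for `session`.
#' @param align_yaw register the horizontal frame by one rotation about z
#'   before computing errors.
#' @return list with `rmse` (named per-foot RMS error, m), `worst` (max of
#'   the two), `yaw_offset` (registration angles, rad), and `n` (samples per
#'   trace).
#' @export
position_accuracy <- function(session, cfg = pipeline_config(),
                              report = NULL, align_yaw = TRUE) {
  if (is.null(session$truth)) stopf("session carries no ground truth")
  if (is.null(report)) report <- run_pipeline(session, cfg)
  rmse <- c(foot_L = NA_real_, foot_R = NA_real_)
  yaw_off <- c(foot_L = 0, foot_R = 0)
  for (nm in names(rmse)) {
    est <- report$feet[[nm]]$position
    tru <- session$truth$segments[[nm]]$pos
    tru <- sweep(tru, 2L, tru[1L, ])
    if (align_yaw) {
      th <- atan2(sum(est[, 1L] * tru[, 2L] - est[, 2L] * tru[, 1L]),
                  sum(est[, 1L] * tru[, 1L] + est[, 2L] * tru[, 2L]))
      est <- cbind(cos(th) * est[, 1L] - sin(th) * est[, 2L],
                   sin(th) * est[, 1L] + cos(th) * est[, 2L],
                   est[, 3L])
      yaw_off[nm] <- th
    }
    err2 <- rowSums((est - tru)^2)
    rmse[nm] <- sqrt(mean(err2))
  }
  list(rmse = rmse, worst = max(rmse), yaw_offset = yaw_off,
       n = nrow(report$feet$foot_L$position))
}
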