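#' Simulate one subject's walking trial
#'
#' Generates paired 9-channel IMU data (at the IMU rate) and noise-free
#' 3-joint reference kinematics (at the kinematic rate) for `n_cycles`
#' consecutive gait cycles. Cycle durations carry multiplicative Gaussian
#' jitter; within each cycle the phase u advances linearly. Joint angles
#' come from the subject's perturbed Fourier templates; pitch, z-gyro and
#' x/y accelerometer channels follow the planar forward-kinematic model
#' plus Gaussian noise; roll and the x/y gyro and z accelerometer are weak
#' gait-phase-locked oscillations plus noise (realistically redundant
#' channels; the cross-talk phases are mounting-dependent, i.e. drawn per
#' subject); yaw is pure noise. Accelerometer and gyro samples are
#' quantised to the configured resolutions. Cycle boundary indices are
#' recorded exactly from the phase-zero crossings in both streams.
#'
#' @param profile A [sample_subject_profile()] result.
#' @param n_cycles Number of gait cycles (>= 1).
#' @param seed Integer seed; the trial is a pure function of
#'   `(profile, n_cycles, seed, config rates)`.
#' @param config A [cohort_config()] (rates, resolutions, dense-grid
#'   factor).
#' @param templates Joint templates, default [default_gait_templates()].
#' @return An object of class `gait_trial`: list with `imu` (data frame
#'   `t_s` + 9 channels), `kin` (data frame `t_s`, `hip_deg`, `knee_deg`,
#'   `ankle_deg`), `imu_boundaries` / `kin_boundaries` (start index of each
#'   cycle plus one-past-the-end sentinel), `subject_id`, `seed`,
#'   `profile`.
#' @export
simulate_trial <- function(profile, n_cycles, seed = 1L,
                           config = cohort_config(),
                           templates = default_gait_templates()) {
  stopifnot(inherits(profile, "subject_profile"), n_cycles >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  stride_t <- 120 / profile$cadence
  durations <- stride_t * pmax(0.5, 1 + stats::rnorm(n_cycles, 0,
                                                     profile$jitter_sd))
  starts <- c(0, cumsum(durations))        # cycle start times, s
  t_total <- starts[n_cycles + 1]

  # continuous phase (in strides): piecewise linear through cycle starts
  phase_at <- function(t) {
    k <- findInterval(t, starts, rightmost.closed = FALSE)
    k <- pmin(pmax(k, 1L), n_cycles)
    (k - 1) + (t - starts[k]) / durations[k]
  }
  angles_at <- function(t) {
    u <- phase_at(t) %% 1
    vapply(joint_names(), function(j) {
      p <- profile$perturb[[j]]
      eval_template_perturbed(templates[[j]], u, p$amp, p$offset, p$phase)
    }, numeric(length(t)))
  }

  # dense grid for finite-difference kinematics
  sim_rate <- config$imu_rate * config$sim_rate_factor
  t_dense <- seq(0, t_total, by = 1 / sim_rate)
  ang_dense <- angles_at(t_dense)
  fk <- shank_forward_kinematics(profile, t_dense,
                                 hip_deg = ang_dense[, "hip"],
                                 knee_deg = ang_dense[, "knee"],
                                 phase = phase_at(t_dense))

  # IMU sampling: dense grid is an exact multiple of the IMU rate
  t_imu <- seq(0, t_total - 1e-9, by = 1 / config$imu_rate)
  ii <- round(t_imu * sim_rate) + 1L
  n_imu <- length(t_imu)
  u_imu <- phase_at(t_imu) %% 1

  quant <- function(x, res) if (res > 0) round(x / res) * res else x
  nz <- function(sd) stats::rnorm(n_imu, 0, sd)
  no <- profile$noise

  imu <- data.frame(
    t_s = t_imu,
    pitch_deg = fk$phi_deg[ii] + nz(no$attitude),
    roll_deg = 2.0 * sin(2 * pi * u_imu + 0.8) + nz(no$attitude),
    yaw_deg = nz(no$attitude),
    gyro_x_dps = 5 * sin(2 * pi * u_imu + profile$aux_phase[["gx"]]),
    gyro_y_dps = 8 * cos(2 * pi * u_imu + profile$aux_phase[["gy"]]),
    gyro_z_dps = fk$gyro_z_dps[ii],
    acc_x_g = fk$acc_x_g[ii],
    acc_y_g = fk$acc_y_g[ii],
    acc_z_g = 0.05 * sin(4 * pi * u_imu + profile$aux_phase[["az"]])
  )
  imu$gyro_x_dps <- quant(imu$gyro_x_dps + nz(no$gyro), config$gyro_res)
  imu$gyro_y_dps <- quant(imu$gyro_y_dps + nz(no$gyro), config$gyro_res)
  imu$gyro_z_dps <- quant(imu$gyro_z_dps + nz(no$gyro), config$gyro_res)
  imu$acc_x_g <- quant(imu$acc_x_g + nz(no$accel), config$accel_res)
  imu$acc_y_g <- quant(imu$acc_y_g + nz(no$accel), config$accel_res)
  imu$acc_z_g <- quant(imu$acc_z_g + nz(no$accel), config$accel_res)

  # reference kinematics: noise-free templates evaluated at exact times
  t_kin <- seq(0, t_total - 1e-9, by = 1 / config$kin_rate)
  ang_kin <- angles_at(t_kin)
  kin <- data.frame(t_s = t_kin, hip_deg = ang_kin[, "hip"],
                    knee_deg = ang_kin[, "knee"],
                    ankle_deg = ang_kin[, "ankle"])

  bnd <- function(ts) {
    b <- vapply(starts, function(s) {
      which(ts >= s - 1e-9)[1]
    }, integer(1))
    b[n_cycles + 1] <- length(ts) + 1L
    as.integer(b)
  }

  structure(list(imu = imu, kin = kin,
                 imu_boundaries = bnd(t_imu), kin_boundaries = bnd(t_kin),
                 subject_id = profile$subject_id, seed = as.integer(seed),
                 profile = profile),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> subject=%d cycles=%d imu_samples=%d kin_samples=%d\n",
    x$subject_id, length(x$imu_boundaries) - 1L, nrow(x$imu), nrow(x$kin)))
  invisible(x)
}

#' Number of gait cycles in a trial
#' @param trial A `gait_trial`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(trial) length(trial$imu_boundaries) - 1L

#' Generate a synthetic walking cohort
#'
#' Draws one subject profile and one trial per subject. Per-subject child
#' seeds derive deterministically from the master seed, so the whole cohort
#' is a pure function of its configuration.
#'
#' @param config A [cohort_config()].
#' @param templates Joint templates, default [default_gait_templates()].
#' @return An object of class `gait_cohort`: list with `trials` (one
#'   `gait_trial` per subject) and `manifest` (config, profiles, seeds).
#' @export
make_cohort <- function(config = cohort_config(),
                        templates = default_gait_templates()) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  profile_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  cycle_counts <- if (length(config$n_cycles) == 2) {
    sample(config$n_cycles[1]:config$n_cycles[2], config$n_subjects,
           replace = TRUE)
  } else rep(as.integer(config$n_cycles), config$n_subjects)

  profiles <- vector("list", config$n_subjects)
  trials <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    profiles[[s]] <- sample_subject_profile(config, subject_id = s,
                                            seed = profile_seeds[s])
    trials[[s]] <- simulate_trial(profiles[[s]], cycle_counts[s],
                                  seed = trial_seeds[s], config = config,
                                  templates = templates)
  }
  manifest <- list(config = unclass(config), profiles = profiles,
                   profile_seeds = profile_seeds, trial_seeds = trial_seeds,
                   cycle_counts = cycle_counts)
  structure(list(trials = trials, manifest = manifest),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  total <- sum(vapply(x$trials, n_cycles, integer(1)))
  cat(sprintf("<gait_cohort> %d subjects, %d total gait cycles\n",
              length(x$trials), total))
  invisible(x)
}
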