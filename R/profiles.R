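#' Cohort generation settings
#'
#' Bundles the acquisition setup and sampling distributions used to generate
#' a synthetic walking cohort. Defaults reproduce the emulated study's
#' acquisition: a 23 Hz 9-channel shank IMU (0.01 g accelerometer and
#' 0.05 deg/s gyroscope resolution) paired with 60 Hz reference kinematics,
#' a cohort of 30 subjects walking at self-selected speed
#' (1.27 +/- 0.13 m/s, cadence 113.87 +/- 7.32 steps/min).
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_cycles Gait cycles recorded per subject (default 16; give a
#'   length-2 vector such as `c(16, 20)` to draw per-subject counts
#'   uniformly from that range).
#' @param imu_rate IMU sampling rate, Hz (default 23).
#' @param kin_rate Reference kinematics sampling rate, Hz (default 60).
#' @param accel_res Accelerometer quantisation step, g (default 0.01).
#' @param gyro_res Gyroscope quantisation step, deg/s (default 0.05).
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param speed_mean,speed_sd Walking-speed distribution, m/s.
#' @param cadence_mean,cadence_sd Cadence distribution, steps/min.
#' @param thigh_mean,thigh_sd,shank_mean,shank_sd Segment-length
#'   distributions, m.
#' @param sensor_offset Sensor distance below the knee along the shank, m.
#' @param accel_noise_sd,gyro_noise_sd,attitude_noise_sd Additive Gaussian
#'   channel noise (g, deg/s, deg).
#' @param jitter_sd Multiplicative cycle-duration jitter SD (fraction).
#' @param amp_sd,offset_sd,phase_sd Per-joint template perturbation SDs:
#'   amplitude scale (about 1), additive offset (deg), phase shift (cycles).
#' @param hip_osc_vert,hip_osc_fore Hip-point oscillation amplitudes at step
#'   (double-stride) frequency, m.
#' @param sim_rate_factor Internal dense simulation grid, as a multiple of
#'   `imu_rate` (default 20, i.e. 460 Hz), so finite-difference
#'   accelerations are accurate.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30, n_cycles = 16,
                          imu_rate = 23, kin_rate = 60,
                          accel_res = 0.01, gyro_res = 0.05,
                          seed = 1L,
                          speed_mean = 1.27, speed_sd = 0.13,
                          cadence_mean = 113.87, cadence_sd = 7.32,
                          thigh_mean = 0.42, thigh_sd = 0.02,
                          shank_mean = 0.41, shank_sd = 0.02,
                          sensor_offset = 0.10,
                          accel_noise_sd = 0.02, gyro_noise_sd = 1.0,
                          attitude_noise_sd = 0.5,
                          jitter_sd = 0.03,
                          amp_sd = 0.08, offset_sd = 2.0, phase_sd = 0.02,
                          hip_osc_vert = 0.02, hip_osc_fore = 0.01,
                          sim_rate_factor = 20) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_cycles = n_cycles,
              imu_rate = imu_rate, kin_rate = kin_rate,
              accel_res = accel_res, gyro_res = gyro_res,
              seed = as.integer(seed),
              speed_mean = speed_mean, speed_sd = speed_sd,
              cadence_mean = cadence_mean, cadence_sd = cadence_sd,
              thigh_mean = thigh_mean, thigh_sd = thigh_sd,
              shank_mean = shank_mean, shank_sd = shank_sd,
              sensor_offset = sensor_offset,
              accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
              attitude_noise_sd = attitude_noise_sd,
              jitter_sd = jitter_sd,
              amp_sd = amp_sd, offset_sd = offset_sd, phase_sd = phase_sd,
              hip_osc_vert = hip_osc_vert, hip_osc_fore = hip_osc_fore,
              sim_rate_factor = sim_rate_factor)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1,
            all(cfg$n_cycles >= 1), length(cfg$n_cycles) %in% 1:2,
            cfg$imu_rate > 0, cfg$kin_rate > 0,
            cfg$accel_res >= 0, cfg$gyro_res >= 0,
            cfg$speed_sd >= 0, cfg$cadence_sd >= 0,
            cfg$thigh_mean > 0, cfg$shank_mean > 0, cfg$sensor_offset > 0,
            cfg$accel_noise_sd >= 0, cfg$gyro_noise_sd >= 0,
            cfg$attitude_noise_sd >= 0, cfg$jitter_sd >= 0,
            cfg$sim_rate_factor >= 4)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d subjects, %s cycles/subject, IMU %g Hz, kin %g Hz, seed %d\n",
    x$n_subjects, paste(x$n_cycles, collapse = "-"), x$imu_rate, x$kin_rate,
    x$seed))
  invisible(x)
}

#' Draw one subject's gait profile
#'
#' Samples walking speed and cadence from the cohort distributions, derives
#' stride length from the identity speed = stride * cadence / 120 (a stride
#' is two steps), and draws segment lengths, per-joint template
#' perturbations and the cycle-duration jitter factor. Draws are clipped to
#' physical bounds (speed >= 0.5 m/s, cadence >= 60 steps/min, lengths
#' >= 0.2 m); clipping is reported with a message.
#'
#' @param config A [cohort_config()].
#' @param subject_id Integer subject identifier.
#' @param seed Integer seed; the draw is a pure function of
#'   `(config, subject_id, seed)`.
#' @return An object of class `subject_profile`.
#' @export
sample_subject_profile <- function(config, subject_id = 1L, seed = 1L) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  clip <- function(x, lo, what) {
    if (x < lo) {
      message(sprintf("subject %d: %s clipped from %.3f to %.3f",
                      subject_id, what, x, lo))
      lo
    } else x
  }
  speed <- clip(stats::rnorm(1, config$speed_mean, config$speed_sd),
                0.5, "speed (m/s)")
  cadence <- clip(stats::rnorm(1, config$cadence_mean, config$cadence_sd),
                  60, "cadence (steps/min)")
  stride <- speed * 120 / cadence
  thigh <- clip(stats::rnorm(1, config$thigh_mean, config$thigh_sd),
                0.2, "thigh length (m)")
  shank <- clip(stats::rnorm(1, config$shank_mean, config$shank_sd),
                0.2, "shank length (m)")

  perturb <- lapply(stats::setNames(joint_names(), joint_names()),
                    function(j) {
    list(amp = stats::rnorm(1, 1, config$amp_sd),
         offset = stats::rnorm(1, 0, config$offset_sd),
         phase = stats::rnorm(1, 0, config$phase_sd))
  })
  # mounting-dependent phases of the out-of-plane cross-talk oscillations
  aux_phase <- stats::setNames(stats::runif(3, 0, 2 * pi),
                               c("gx", "gy", "az"))

  structure(list(
    subject_id = as.integer(subject_id),
    speed = speed, cadence = cadence, stride = stride,
    thigh_length = thigh, shank_length = shank,
    sensor_offset = config$sensor_offset,
    perturb = perturb, aux_phase = aux_phase,
    noise = list(accel = config$accel_noise_sd,
                 gyro = config$gyro_noise_sd,
                 attitude = config$attitude_noise_sd),
    jitter_sd = config$jitter_sd,
    hip_osc_vert = config$hip_osc_vert,
    hip_osc_fore = config$hip_osc_fore,
    seed = as.integer(seed)
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> id=%d speed=%.2f m/s cadence=%.1f steps/min stride=%.2f m\n",
    x$subject_id, x$speed, x$cadence, x$stride))
  invisible(x)
}

# Save/restore the global RNG stream so seeded helpers do not disturb the
# caller's randomness.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
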