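# Shared fixture builders. Everything is generated in code; "quiet"
# configurations turn off every stochastic ingredient so tests can rely on
# exact periodicity. Cadence 115 steps/min makes one stride exactly
# 24 IMU samples (120/115 s * 23 Hz), so discrete sums over a cycle are
# exact quadrature for the band-limited templates.

quiet_config <- function(n_subjects = 1, cadence = 115, seed = 1L, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed,
                accel_noise_sd = 0, gyro_noise_sd = 0,
                attitude_noise_sd = 0, jitter_sd = 0,
                accel_res = 0, gyro_res = 0,
                cadence_mean = cadence, cadence_sd = 0, speed_sd = 0,
                amp_sd = 0, offset_sd = 0, phase_sd = 0, ...)
}

quiet_trial <- function(n_cycles = 6, cadence = 115, seed = 2L,
                        profile_seed = 11L) {
  cfg <- quiet_config(cadence = cadence)
  p <- sample_subject_profile(cfg, subject_id = 1L, seed = profile_seed)
  simulate_trial(p, n_cycles, seed = seed, config = cfg)
}

# a small synthetic gait_cycle with prescribed feature/label matrices
toy_cycle <- function(features, labels, subject_id = 1L, cycle_id = 1L) {
  colnames(features) <- imu_channels()[seq_len(ncol(features))]
  colnames(labels) <- joint_names()[seq_len(ncol(labels))]
  structure(list(subject_id = subject_id, cycle_id = cycle_id,
                 features = features, labels = labels),
            class = "gait_cycle")
}

# random cycles with n samples and 9 features / 3 labels
random_cycles <- function(n_cycles, n = 24, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_cycles), function(k) {
    toy_cycle(matrix(rnorm(n * 9), n, 9), matrix(rnorm(n * 3), n, 3),
              subject_id = 1L, cycle_id = k)
  })
}
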