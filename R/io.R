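# Plain-CSV dialects for the paired sensor/kinematics streams, and the
# cohort manifest. All angles are degrees, accelerations g, angular
# velocities deg/s; '.' decimal separator, UTF-8, header row.

imu_csv_cols <- c("subject_id", "trial_id", "cycle_id", "sample_idx", "t_s",
                  "pitch_deg", "roll_deg", "yaw_deg", "gyro_x_dps",
                  "gyro_y_dps", "gyro_z_dps", "acc_x_g", "acc_y_g",
                  "acc_z_g")
kin_csv_cols <- c("subject_id", "trial_id", "cycle_id", "sample_idx", "t_s",
                  "hip_deg", "knee_deg", "ankle_deg")

cycle_id_per_row <- function(n_rows, boundaries) {
  rep(seq_len(length(boundaries) - 1L), diff(boundaries))
}

trial_imu_frame <- function(trial) {
  data.frame(subject_id = trial$subject_id, trial_id = 1L,
             cycle_id = cycle_id_per_row(nrow(trial$imu),
                                         trial$imu_boundaries),
             sample_idx = seq_len(nrow(trial$imu)) - 1L,
             trial$imu, check.names = FALSE)
}

trial_kin_frame <- function(trial) {
  data.frame(subject_id = trial$subject_id, trial_id = 1L,
             cycle_id = cycle_id_per_row(nrow(trial$kin),
                                         trial$kin_boundaries),
             sample_idx = seq_len(nrow(trial$kin)) - 1L,
             trial$kin, check.names = FALSE)
}

#' Write a cohort to a directory
#'
#' Writes `imu.csv` and `kin.csv` in the package's documented dialects and
#' `manifest.json` (configuration, per-subject profiles and seeds).
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imu <- do.call(rbind, lapply(cohort$trials, trial_imu_frame))
  kin <- do.call(rbind, lapply(cohort$trials, trial_kin_frame))
  utils::write.csv(imu, file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(kin, file.path(dir, "kin.csv"), row.names = FALSE)
  manifest <- cohort$manifest
  manifest$profiles <- lapply(manifest$profiles, unclass)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

check_csv <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[cols]))
  if (length(bad)) {
    stop(sprintf("%s: NA/NaN cell(s) at data row %d", path, bad[1]))
  }
  # timestamps must advance within each subject/trial
  key <- interaction(df$subject_id, df$trial_id, drop = TRUE)
  for (g in split(seq_len(nrow(df)), key)) {
    dt <- diff(df$t_s[g])
    if (any(dt <= 0)) {
      stop(sprintf("%s: non-monotone timestamps at data row %d", path,
                   g[which(dt <= 0)[1] + 1L]))
    }
  }
  df[cols]
}

#' Read the IMU / kinematics CSV dialects
#'
#' Column order and units are enforced; missing columns, NA cells and
#' non-monotone timestamps within a trial are rejected with the offending
#' row.
#'
#' @param path CSV file path.
#' @return Data frame in the documented column order.
#' @export
read_imu_csv <- function(path) {
  check_csv(utils::read.csv(path), imu_csv_cols, path)
}

#' @rdname read_imu_csv
#' @export
read_kin_csv <- function(path) {
  check_csv(utils::read.csv(path), kin_csv_cols, path)
}

boundaries_from_cycle_id <- function(cycle_id) {
  starts <- which(c(TRUE, diff(cycle_id) != 0))
  as.integer(c(starts, length(cycle_id) + 1L))
}

#' Write / read preprocessed cycles as a flat CSV
#'
#' One row per sample, keyed by subject, cycle and sample index, with the
#' nine feature columns ([imu_channels()]) and three label columns
#' ([joint_names()]).
#'
#' @param cycles List of `gait_cycle` objects.
#' @param path CSV file path.
#' @return `read_cycles_csv` returns the list of `gait_cycle` objects.
#' @export
write_cycles_csv <- function(cycles, path) {
  rows <- do.call(rbind, lapply(cycles, function(cy) {
    data.frame(subject_id = cy$subject_id, cycle_id = cy$cycle_id,
               sample_idx = seq_len(nrow(cy$features)) - 1L,
               cy$features, cy$labels, check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycles_csv
#' @export
read_cycles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", "cycle_id", "sample_idx", imu_channels(),
            joint_names())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  keys <- unique(df[c("subject_id", "cycle_id")])   # file order
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- which(df$subject_id == keys$subject_id[i] &
                    df$cycle_id == keys$cycle_id[i])
    structure(list(subject_id = keys$subject_id[i],
                   cycle_id = keys$cycle_id[i],
                   features = as.matrix(df[rows, imu_channels()]),
                   labels = as.matrix(df[rows, joint_names()])),
              class = "gait_cycle")
  })
}

#' Assemble trials from paired CSV streams
#'
#' Rebuilds `gait_trial` objects (one per subject/trial pair) from the two
#' CSV dialects, recovering cycle boundaries from the `cycle_id` column.
#'
#' @param imu_path,kin_path Paths to `imu.csv` and `kin.csv`.
#' @return List of `gait_trial` objects.
#' @export
read_trials <- function(imu_path, kin_path) {
  imu <- read_imu_csv(imu_path)
  kin <- read_kin_csv(kin_path)
  keys <- unique(imu[c("subject_id", "trial_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    s <- keys$subject_id[i]; tr <- keys$trial_id[i]
    mi <- imu[imu$subject_id == s & imu$trial_id == tr, ]
    mk <- kin[kin$subject_id == s & kin$trial_id == tr, ]
    if (nrow(mk) == 0) {
      stop(sprintf("no kinematic rows for subject %s trial %s", s, tr))
    }
    structure(list(
      imu = mi[, c("t_s", "pitch_deg", "roll_deg", "yaw_deg",
                   "gyro_x_dps", "gyro_y_dps", "gyro_z_dps",
                   "acc_x_g", "acc_y_g", "acc_z_g")],
      kin = mk[, c("t_s", "hip_deg", "knee_deg", "ankle_deg")],
      imu_boundaries = boundaries_from_cycle_id(mi$cycle_id),
      kin_boundaries = boundaries_from_cycle_id(mk$cycle_id),
      subject_id = as.integer(s), seed = NA_integer_, profile = NULL),
      class = "gait_trial")
  })
}
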