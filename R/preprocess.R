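# Signal conditioning: zero-phase low-pass filtering of the reference
# kinematics, median smoothing of the IMU channels, per-cycle label
# resampling onto the IMU sample grid, and min-max input normalisation.

# Direct-form II transposed IIR filter with initial state. zi is the
# steady-state unit-step state (lfilter_zi), scaled by the first sample so
# a constant input produces a constant output from sample one.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(a) - 1L
  z <- if (is.null(zi)) numeric(n) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1) {
      for (j in 1:(n - 1)) {
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
      }
    }
    z[n] <- b[n + 1] * xi - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit step input (companion-matrix solve).
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- matrix(0, n, n)
  A[, 1] <- -a[2:(n + 1)]
  if (n > 1) A[1:(n - 1), 2:n] <- diag(n - 1)
  B <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  solve(diag(n) - A, B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter (via [signal::butter()])
#' and applies it forward and backward, giving zero phase shift and a
#' squared magnitude response. Edges are handled with odd-reflection
#' padding and steady-state initial conditions, so a constant signal passes
#' through unchanged and edge transients are suppressed.
#'
#' @param x Uniformly sampled signal.
#' @param fs Sampling rate, Hz.
#' @param fc Cutoff frequency, Hz (default 4).
#' @param order Filter order (default 4); the effective order after the
#'   two passes is doubled.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, fc = 4, order = 4) {
  if (fc >= fs / 2) {
    stop(sprintf("cutoff fc = %g Hz must be below the Nyquist rate %g Hz",
                 fc, fs / 2))
  }
  flt <- signal::butter(order, fc / (fs / 2), type = "low")
  b <- flt$b
  a <- flt$a
  padlen <- 3L * (length(a) - 1L) + 3L
  if (length(x) <= padlen) {
    stop(sprintf(
      "signal too short to filter: need more than %d samples, got %d",
      padlen, length(x)))
  }
  n <- length(x)
  # odd reflection about the end samples
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Median smoothing with reflected padding
#'
#' Each output sample is the median of an odd-length window centred on it;
#' the signal is extended by reflection (excluding the edge sample) so the
#' output has the input's length.
#'
#' @param x Signal.
#' @param window Odd window length (default 5).
#' @return Smoothed signal, same length.
#' @export
median_smooth <- function(x, window = 5) {
  if (window %% 2 == 0 || window < 1) {
    stop("median window must be odd and >= 1")
  }
  n <- length(x)
  if (n < window) stop("signal shorter than the median window")
  if (window == 1) return(x)
  h <- (window - 1L) %/% 2L
  ext <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  vapply(seq_len(n), function(i) {
    stats::median(ext[i:(i + window - 1L)])
  }, numeric(1))
}

#' Resample one cycle's labels onto the IMU sample grid
#'
#' Linearly interpolates a cycle's kinematic samples on normalised cycle
#' time [0, 1] down (or up) to `n_imu` equispaced samples, preserving the
#' first and last samples exactly. Set `method = "cubic"` for natural
#' cubic-spline interpolation.
#'
#' @param kin_cycle Numeric vector or matrix (samples x joints) at the
#'   kinematic rate.
#' @param n_imu Target sample count (>= 2).
#' @param method `"linear"` (default) or `"cubic"`.
#' @return Vector or matrix with `n_imu` samples.
#' @export
resample_cycle_labels <- function(kin_cycle, n_imu, method = "linear") {
  method <- match.arg(method, c("linear", "cubic"))
  vec <- is.null(dim(kin_cycle))
  m <- if (vec) matrix(kin_cycle, ncol = 1) else as.matrix(kin_cycle)
  if (nrow(m) < 2) stop("kinematic cycle needs at least 2 samples")
  if (n_imu < 2) stop("target sample count n_imu must be >= 2")
  u_src <- seq(0, 1, length.out = nrow(m))
  u_dst <- seq(0, 1, length.out = n_imu)
  out <- apply(m, 2, function(col) {
    if (method == "linear") {
      stats::approx(u_src, col, xout = u_dst)$y
    } else {
      stats::spline(u_src, col, xout = u_dst, method = "natural")$y
    }
  })
  out <- matrix(out, nrow = n_imu, dimnames = list(NULL, colnames(m)))
  if (vec) drop(out) else out
}

#' Fit per-feature min-max normalisation statistics
#'
#' Records each feature's minimum and maximum over the training cycles, for
#' scaling inputs to the 0-1 range: X = (X_orig - X_min) / (X_max - X_min).
#' Statistics are fitted on the training split only and applied unchanged
#' to test data (no clamping), so test features may fall outside [0, 1].
#' A constant training feature (X_max == X_min) is flagged and maps to 0.
#'
#' @param train_cycles List of `gait_cycle` objects (see [build_cycles()]),
#'   or a single numeric feature matrix.
#' @return Object of class `norm_stats` with `xmin`, `xmax`, `constant`.
#' @export
fit_minmax <- function(train_cycles) {
  if (is.matrix(train_cycles)) train_cycles <- list(
    list(features = train_cycles))
  if (length(train_cycles) == 0) stop("empty training set")
  X <- do.call(rbind, lapply(train_cycles, function(cy) cy$features))
  xmin <- apply(X, 2, min)
  xmax <- apply(X, 2, max)
  constant <- xmax <= xmin
  if (any(constant)) {
    warning(sprintf("constant training feature(s): %s (mapped to 0)",
                    paste(colnames(X)[constant], collapse = ", ")))
  }
  structure(list(xmin = xmin, xmax = xmax, constant = constant),
            class = "norm_stats")
}

#' Apply min-max normalisation
#' @param x Feature matrix (samples x features), columns in the order the
#'   statistics were fitted on.
#' @param stats A [fit_minmax()] result.
#' @return Normalised matrix, same shape.
#' @export
apply_minmax <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"), ncol(x) == length(stats$xmin))
  rng <- stats$xmax - stats$xmin
  rng[stats$constant] <- 1
  out <- sweep(sweep(x, 2, stats$xmin, "-"), 2, rng, "/")
  out[, stats$constant] <- 0
  out
}

#' Invert min-max normalisation
#' @param x Normalised matrix.
#' @param stats A [fit_minmax()] result.
#' @return Matrix on the original scale (constant features are restored to
#'   their fitted value).
#' @export
invert_minmax <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"), ncol(x) == length(stats$xmin))
  rng <- stats$xmax - stats$xmin
  rng[stats$constant] <- 0
  sweep(sweep(x, 2, rng, "*"), 2, stats$xmin, "+")
}

#' Cut a trial into aligned gait cycles
#'
#' Conditions a trial's signals and aligns the kinematic labels with the
#' IMU samples cycle by cycle: the three joint-angle streams are low-pass
#' filtered at the kinematic rate (zero-phase Butterworth), the nine IMU
#' channels are median-smoothed over the whole trial, both streams are cut
#' at the recorded cycle boundaries, and each cycle's labels are resampled
#' to that cycle's IMU sample count. Cycle lengths differ between cycles
#' and subjects; nothing is padded.
#'
#' Each cycle's labels end up with exactly that cycle's IMU sample count.
#' With the default `label_alignment = "time"` the filtered label streams
#' are interpolated at the IMU sample instants, so a label is the joint
#' angle at the exact moment its feature row was sensed. The
#' `"normalized"` variant instead maps the cycle's kinematic samples onto
#' the cycle's IMU samples on a normalised 0-1 grid
#' ([resample_cycle_labels()]); because a cycle's first IMU sample falls up
#' to one sample period after the true cycle start, that variant carries a
#' per-cycle phase error of up to ~4 percent of a sample period's phase,
#' i.e. several degrees at the fast-moving knee.
#'
#' @param trial A `gait_trial`.
#' @param cutoff,order Butterworth low-pass parameters for the labels
#'   (default 4 Hz, order 4).
#' @param median_window Median-smoothing window for IMU channels
#'   (default 5).
#' @param resample_method Passed to [resample_cycle_labels()] (interp
#'   method for either alignment).
#' @param label_alignment `"time"` (default) or `"normalized"`, see above.
#' @return List of `gait_cycle` objects: each has `subject_id`, `cycle_id`,
#'   `features` (n x 9 matrix, [imu_channels()] order) and `labels`
#'   (n x 3 matrix, [joint_names()] order).
#' @export
build_cycles <- function(trial, cutoff = 4, order = 4, median_window = 5,
                         resample_method = "linear",
                         label_alignment = c("time", "normalized")) {
  label_alignment <- match.arg(label_alignment)
  stopifnot(inherits(trial, "gait_trial"))
  nb <- length(trial$imu_boundaries)
  stopifnot(nb >= 2)

  imu_cols <- c("pitch_deg", "roll_deg", "yaw_deg", "gyro_x_dps",
                "gyro_y_dps", "gyro_z_dps", "acc_x_g", "acc_y_g", "acc_z_g")
  feats <- as.matrix(trial$imu[, imu_cols])
  colnames(feats) <- imu_channels()
  feats <- apply(feats, 2, median_smooth, window = median_window)

  lab_cols <- c("hip_deg", "knee_deg", "ankle_deg")
  labs <- as.matrix(trial$kin[, lab_cols])
  colnames(labs) <- joint_names()
  labs <- apply(labs, 2, butterworth_lowpass, fs = attr_kin_rate(trial),
                fc = cutoff, order = order)

  cycles <- list()
  for (k in seq_len(nb - 1L)) {
    i0 <- trial$imu_boundaries[k]
    i1 <- trial$imu_boundaries[k + 1L] - 1L
    j0 <- trial$kin_boundaries[k]
    j1 <- trial$kin_boundaries[k + 1L] - 1L
    if (i1 - i0 + 1L < 2L || j1 - j0 + 1L < 2L) {
      warning(sprintf("subject %d cycle %d has < 2 samples; skipped",
                      trial$subject_id, k))
      next
    }
    f <- feats[i0:i1, , drop = FALSE]
    l <- if (label_alignment == "time") {
      t_imu <- trial$imu$t_s[i0:i1]
      t_kin <- trial$kin$t_s
      out <- vapply(joint_names(), function(j) {
        if (resample_method == "linear") {
          stats::approx(t_kin, labs[, j], xout = t_imu, rule = 2)$y
        } else {
          stats::spline(t_kin, labs[, j], xout = t_imu,
                        method = "natural")$y
        }
      }, numeric(length(t_imu)))
      matrix(out, ncol = 3, dimnames = list(NULL, joint_names()))
    } else {
      resample_cycle_labels(labs[j0:j1, , drop = FALSE], nrow(f),
                            method = resample_method)
    }
    cycles[[length(cycles) + 1L]] <- structure(
      list(subject_id = trial$subject_id, cycle_id = k,
           features = f, labels = l),
      class = "gait_cycle")
  }
  cycles
}

# kinematic rate from the trial's time stamps
attr_kin_rate <- function(trial) {
  round(1 / stats::median(diff(trial$kin$t_s)))
}

#' Detect gait-cycle boundaries from the mediolateral gyro
#'
#' Optional utility for data without recorded cycle boundaries: boundaries
#' are placed at the prominent once-per-stride peaks of the (median
#' smoothed) mediolateral gyro channel, the landmark at the simulator's
#' phase origin.
#'
#' @param gyro_z Mediolateral gyro signal, deg/s.
#' @param rate Sampling rate, Hz.
#' @param min_height Peak acceptance threshold as a fraction of the largest
#'   peak (default 0.5).
#' @return Integer vector of boundary sample indices (possibly empty).
#' @export
detect_cycles_gyro <- function(gyro_z, rate, min_height = 0.5) {
  n <- length(gyro_z)
  if (n < 2 * rate) stop("need at least 2 s of data")
  g <- median_smooth(gyro_z, 5)
  if (max(g) - min(g) < 1e-9) return(integer(0))
  # one contiguous super-threshold region per stride; its argmax is the
  # boundary (robust to the flat-topped peaks median smoothing produces)
  thr <- min(g) + min_height * (max(g) - min(g))
  above <- g >= thr
  edges <- diff(c(FALSE, above, FALSE))
  reg_start <- which(edges == 1)
  reg_end <- which(edges == -1) - 1L
  # a region clipped by the end of the recording is an incomplete stride
  if (length(reg_start) && reg_end[length(reg_end)] == n) {
    reg_start <- reg_start[-length(reg_start)]
    reg_end <- reg_end[-length(reg_end)]
  }
  vapply(seq_along(reg_start), function(r) {
    span <- reg_start[r]:reg_end[r]
    span[which.max(g[span])]
  }, integer(1))
}
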