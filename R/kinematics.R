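#' Planar forward kinematics of the shank-mounted sensor
#'
#' Computes what an ideal sagittal-plane IMU fixed to the shank would sense,
#' given hip and knee flexion trajectories on a uniform dense time grid.
#' The model is planar with the trunk vertical: thigh inclination from
#' vertical equals hip flexion, and shank inclination is
#' phi = hip - knee. The hip point advances at constant walking speed with
#' small vertical and fore-aft oscillations at step (double-stride)
#' frequency; the sensor sits `sensor_offset` metres below the knee along
#' the shank.
#'
#' Sensor frame: x longitudinal pointing distal (down the shank), y
#' anterior, z mediolateral. Specific force is (linear acceleration minus
#' gravity) rotated into that frame and expressed in g; at rest the
#' longitudinal axis therefore reads -1 g (it points down while the
#' reaction is up). Angular velocity d(phi)/dt appears on the z gyro.
#' Accelerations and angular velocity are obtained by central finite
#' differences on the dense grid (one-sided at the ends).
#'
#' @param profile A [sample_subject_profile()] result (segment lengths,
#'   speed, oscillation amplitudes are read from it).
#' @param t Uniform, strictly increasing time grid (s), dense relative to
#'   gait (>= 200 Hz recommended).
#' @param hip_deg,knee_deg Hip and knee flexion at `t`, degrees.
#' @param phase Optional gait phase (strides) at `t`, used only to lock the
#'   hip-point oscillations to the gait cycle; defaults to
#'   `t * cadence / 120`.
#' @return List with `phi_deg` (shank inclination), `gyro_z_dps`,
#'   `acc_x_g`, `acc_y_g`, each the length of `t`.
#' @export
shank_forward_kinematics <- function(profile, t, hip_deg, knee_deg,
                                     phase = NULL) {
  n <- length(t)
  stopifnot(n >= 3, length(hip_deg) == n, length(knee_deg) == n)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1e-12)) || any(dt <= 0)) {
    stop("time grid must be uniform and strictly increasing")
  }
  dt <- dt[1]
  if (is.null(phase)) phase <- t * profile$cadence / 120

  g <- 9.80665
  deg2rad <- pi / 180
  phi <- hip_deg - knee_deg           # shank inclination from vertical, deg
  hip_r <- hip_deg * deg2rad
  phi_r <- phi * deg2rad

  # hip-point trajectory: forward progression + phase-locked oscillations
  # at step (double-stride) frequency
  hx <- profile$speed * t + profile$hip_osc_fore * sin(4 * pi * phase + 0.6)
  hz <- profile$hip_osc_vert * sin(4 * pi * phase + 2.1)

  # sensor position: hip point + thigh vector + offset along the shank
  sx <- hx + profile$thigh_length * sin(hip_r) +
    profile$sensor_offset * sin(phi_r)
  sz <- hz - profile$thigh_length * cos(hip_r) -
    profile$sensor_offset * cos(phi_r)

  cdiff <- function(x) {
    d <- numeric(length(x))
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d
  }
  cdiff2 <- function(x) {
    d <- numeric(length(x))
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    d[1] <- d[2]
    d[n] <- d[n - 1]
    d
  }

  ax <- cdiff2(sx)                    # world-frame sensor acceleration
  az <- cdiff2(sz)
  fx_w <- ax                          # specific force, world frame (m/s^2)
  fz_w <- az + g                      # minus gravity (0, -g)

  # rotate into the sensor frame
  ex <- cbind(sin(phi_r), -cos(phi_r))   # longitudinal, distal
  ey <- cbind(cos(phi_r), sin(phi_r))    # anterior
  acc_x <- (fx_w * ex[, 1] + fz_w * ex[, 2]) / g
  acc_y <- (fx_w * ey[, 1] + fz_w * ey[, 2]) / g

  list(phi_deg = phi, gyro_z_dps = cdiff(phi), acc_x_g = acc_x,
       acc_y_g = acc_y)
}
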