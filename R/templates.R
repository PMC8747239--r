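#' Canonical IMU channel order
#'
#' The nine channels of the shank IMU in the fixed column order used
#' throughout the package: fused attitude (pitch, roll, yaw; degrees),
#' 3-axis gyroscope (deg/s) and 3-axis accelerometer (g). The sensor frame
#' is planar-sagittal: x longitudinal (distal along the shank), y anterior,
#' z mediolateral.
#'
#' @return Character vector of length 9.
#' @export
imu_channels <- function() {
  c("pitch", "roll", "yaw", "gx", "gy", "gz", "ax", "ay", "az")
}

#' Joint names in canonical order
#' @return Character vector `c("hip", "knee", "ankle")`.
#' @export
joint_names <- function() c("hip", "knee", "ankle")

#' Construct a Fourier-series gait template
#'
#' A joint-angle trajectory over one gait cycle, represented as a truncated
#' Fourier series on normalised cycle phase u in [0, 1):
#' \deqn{f(u) = a_0 + \sum_{k=1}^{K} a_k \cos(2\pi k u) + b_k \sin(2\pi k u)}
#' The Fourier form makes the trajectory and all its derivatives periodic by
#' construction, so consecutive simulated cycles join smoothly.
#'
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param a0 Mean angle over the cycle (degrees).
#' @param a,b Numeric vectors of cosine / sine coefficients (degrees),
#'   equal length K.
#' @return An object of class `gait_template`.
#' @export
gait_template <- function(joint, a0, a, b) {
  joint <- match.arg(joint, joint_names())
  stopifnot(length(a) == length(b), is.finite(a0), all(is.finite(a)),
            all(is.finite(b)))
  structure(list(joint = joint, a0 = a0, a = a, b = b),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("<gait_template> joint=%s K=%d a0=%.2f deg\n",
              x$joint, length(x$a), x$a0))
  invisible(x)
}

#' Evaluate a gait template at normalised cycle phase
#'
#' @param template A [gait_template()].
#' @param u Numeric vector of phases, each in [0, 1). Callers must wrap
#'   phase themselves; out-of-range values are an error, not wrapped.
#' @return Joint angle(s) in degrees.
#' @export
joint_angle_template <- function(u, template) {
  stopifnot(inherits(template, "gait_template"))
  if (any(!is.finite(u)) || any(u < 0 | u >= 1)) {
    stop("phase u must lie in [0, 1); wrap phase before calling")
  }
  v <- rep(template$a0, length(u))
  for (k in seq_along(template$a)) {
    v <- v + template$a[k] * cos(2 * pi * k * u) +
      template$b[k] * sin(2 * pi * k * u)
  }
  v
}

# Default templates: normative sagittal hip/knee/ankle trajectories,
# 6 harmonics, phase origin placed at the peak of the shank angular
# velocity d(hip - knee)/du so that the gyro-based cycle detector and the
# simulator's exact boundaries agree. Ranges over a full cycle:
# hip [-10, 32], knee [4, 63], ankle [-18, 15] deg.
.default_template_coefs <- list(
  hip = list(
    a0 = 13.6864,
    a = c(9.1008, 3.3224, -0.0572, 0.0292, 0.0377, -0.0178),
    b = c(17.8253, -1.2099, -0.2027, 0.3075, 0.0378, 0.0094)),
  knee = list(
    a0 = 21.9982,
    a = c(15.7815, 4.4782, -0.0531, -0.9529, -0.1256, 0.2189),
    b = c(-11.0075, -16.5181, -2.8234, -0.9974, -0.5501, -0.1079)),
  ankle = list(
    a0 = -0.0123,
    a = c(-3.2404, 5.3002, 3.7511, 0.1849, -0.0817, -0.0051),
    b = c(-0.1182, 8.8598, -1.9699, -1.9694, -0.3041, 0.1171))
)

#' Default joint-angle templates
#'
#' Normative sagittal-plane hip, knee and ankle trajectories for overground
#' walking at self-selected speed, as 6-harmonic Fourier templates. The
#' phase origin u = 0 is the within-cycle peak of the shank angular
#' velocity (mediolateral gyro), the landmark the cycle detector uses.
#'
#' @return Named list of three [gait_template()] objects.
#' @export
default_gait_templates <- function() {
  lapply(stats::setNames(joint_names(), joint_names()), function(j) {
    cf <- .default_template_coefs[[j]]
    gait_template(j, cf$a0, cf$a, cf$b)
  })
}

# Evaluate a template with per-subject perturbation: amplitude scaling of
# the deviation from the cycle mean, additive offset, and phase shift.
eval_template_perturbed <- function(template, u, amp = 1, offset = 0,
                                    phase = 0) {
  base <- joint_angle_template((u + phase) %% 1, template)
  template$a0 + amp * (base - template$a0) + offset
}
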