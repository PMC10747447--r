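#' Motion profile for a simulated trial
#'
#' Describes one repetition of a task as a smooth raised-cosine
#' rise -- hold -- raised-cosine return of its primary joint angle. The
#' profile starts and ends at 0 degrees (neutral) and attains a single
#' extremum of magnitude `peak_deg`, so the max--min section logic used for
#' temporal alignment is well posed.
#'
#' @param task `"side_dip_left"` (trunk bends left, angle positive),
#'   `"side_dip_right"` (negative), or `"ybt_hip_extension"` (unsigned hip
#'   angle of the reaching leg).
#' @param peak_deg peak angle magnitude in degrees, in (0, 180].
#' @param duration_s trial duration in seconds.
#' @param rate_hz sample rate in Hz.
#' @param hold_fraction fraction of the duration spent holding the peak,
#'   in \[0, 1).
#' @return An object of class `motion_profile`.
#' @examples
#' motion_profile("side_dip_left", peak_deg = 40)
#' @export
motion_profile <- function(task = c("side_dip_left", "side_dip_right",
                                    "ybt_hip_extension"),
                           peak_deg = 40, duration_s = 5, rate_hz = 12,
                           hold_fraction = 0.2) {
  task <- match.arg(task)
  if (!is.finite(peak_deg) || peak_deg <= 0 || peak_deg > 180) {
    stopf("peak_deg must lie in (0, 180]")
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stopf("duration_s must be > 0")
  }
  if (!is.finite(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  if (!is.finite(hold_fraction) || hold_fraction < 0 || hold_fraction >= 1) {
    stopf("hold_fraction must lie in [0, 1)")
  }
  structure(
    list(task = task, peak_deg = peak_deg, duration_s = duration_s,
         rate_hz = rate_hz, hold_fraction = hold_fraction),
    class = "motion_profile"
  )
}

#' Sample the angle profile of a motion
#'
#' Evaluates a [motion_profile()] on its uniform time grid. The trace has
#' `round(duration_s * rate_hz) + 1` samples, is exactly 0 at both ends and
#' reaches `peak_deg` during the hold. Side dips to the right are negated
#' (left-positive convention).
#'
#' @param profile a [motion_profile()].
#' @param rate_hz optional override of the profile's sample rate (used to
#'   derive the high-rate reference grid of the same motion).
#' @return An [angle_trace()].
#' @examples
#' tr <- generate_angle_profile(motion_profile("side_dip_left"))
#' max(tr$angle_deg)
#' @export
generate_angle_profile <- function(profile, rate_hz = NULL) {
  stopifnot(inherits(profile, "motion_profile"))
  rate <- rate_hz %||% profile$rate_hz
  if (!is.finite(rate) || rate <= 0) stopf("rate_hz must be > 0")
  n <- round(profile$duration_s * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  a <- profile_value(t, profile$duration_s, profile$peak_deg,
                     profile$hold_fraction)
  if (profile$task == "side_dip_right") a <- -a
  angle_trace(a, rate_hz = rate, task = profile$task, time_s = t)
}

## Raised-cosine rise / hold / raised-cosine return, vectorised over t.
profile_value <- function(t, duration, peak, hold_fraction) {
  ramp <- (1 - hold_fraction) * duration / 2
  t_hold_end <- duration - ramp
  a <- numeric(length(t))
  rise <- t < ramp
  a[rise] <- peak / 2 * (1 - cos(pi * t[rise] / ramp))
  hold <- t >= ramp & t <= t_hold_end
  a[hold] <- peak
  ret <- t > t_hold_end
  a[ret] <- peak / 2 * (1 - cos(pi * (duration - t[ret]) / ramp))
  ## endpoints are neutral by construction; force exactness against rounding
  a[t <= 0 | t >= duration] <- 0
  a
}

#' Pose a skeleton from an angle trace
#'
#' Forward kinematics of the seven-keypoint model. For side dips the
#' shoulder line is rotated about the anterior axis through the neck (left
#' shoulder drops for positive angles); for the Y-balance reach the right
#' femur is rotated posteriorly in the torso sagittal plane, with the knee
#' kept extended. The construction is angle-consistent with the angle
#' extraction in [angle_trace_from_skeleton()]: extracting the task angle
#' from the posed skeleton returns the input trace to numerical precision.
#'
#' @param params a [skeleton_params()].
#' @param trace an [angle_trace()] driving the motion.
#' @param task task kind; defaults to the trace's task.
#' @return A `skeleton_series`: list with `xyz` (frames x keypoints x 3
#'   array, metres), `rate_hz` and `time_s`.
#' @examples
#' sk <- forward_kinematics(skeleton_params(),
#'                          generate_angle_profile(motion_profile()))
#' dim(sk$xyz)
#' @export
forward_kinematics <- function(params, trace, task = trace$task) {
  stopifnot(inherits(params, "skeleton_params"),
            inherits(trace, "angle_trace"))
  if (!task %in% c("side_dip_left", "side_dip_right", "ybt_hip_extension")) {
    stopf("unknown task: %s", task)
  }
  ang <- trace$angle_deg
  if (!length(ang)) stopf("empty angle trace")
  n <- length(ang)
  kp <- mvk_keypoints()
  xyz <- array(NA_real_, dim = c(n, length(kp), 3L),
               dimnames = list(NULL, kp, c("x", "y", "z")))

  root <- params$root
  hw <- params$hip_halfwidth_m
  sw <- params$shoulder_halfwidth_m
  hip_R <- root + c(0, -hw, 0)
  hip_L <- root + c(0, hw, 0)
  neck <- root + c(0, 0, params$torso_m)

  ## torso axes as seen by the angle extraction (right hip is the used joint)
  sh_L0 <- neck + c(0, sw, 0)
  sh_R0 <- neck + c(0, -sw, 0)
  fr <- torso_frame(neck, sh_L0, sh_R0, hip_R)

  for (i in seq_len(n)) {
    th <- deg2rad(ang[i])
    if (is.na(th)) next
    if (task %in% c("side_dip_left", "side_dip_right")) {
      ## unit vector from right to left shoulder, tilted about the anterior
      ## axis: left shoulder lower for positive (left) side bend
      u <- c(0, cos(th), -sin(th))
      sh_L <- neck + sw * u
      sh_R <- neck - sw * u
      d_fem <- c(0, 0, -1)
    } else {
      sh_L <- sh_L0
      sh_R <- sh_R0
      ## femur rotated from -Z toward -X (posterior) in the torso sagittal
      ## plane; extracted hip angle equals th by construction
      d_fem <- -cos(th) * fr$Z - sin(th) * fr$X
    }
    knee <- hip_R + params$femur_m * d_fem
    ankle <- knee + params$tibia_m * d_fem # knee held extended
    xyz[i, "neck", ] <- neck
    xyz[i, "shoulder_L", ] <- sh_L
    xyz[i, "shoulder_R", ] <- sh_R
    xyz[i, "hip_R", ] <- hip_R
    xyz[i, "hip_L", ] <- hip_L
    xyz[i, "knee_R", ] <- knee
    xyz[i, "ankle_R", ] <- ankle
  }
  skeleton_series(xyz, rate_hz = trace$rate_hz, time_s = trace$time_s)
}

#' Construct a 3D skeleton series
#'
#' @param xyz frames x keypoints x 3 array of world coordinates (m); missing
#'   observations are `NA`.
#' @param rate_hz sample rate (Hz).
#' @param time_s optional time stamps; defaults to a uniform grid.
#' @param residual_px optional frames x keypoints matrix of RMS reprojection
#'   residuals from triangulation.
#' @return An object of class `skeleton_series`.
#' @export
skeleton_series <- function(xyz, rate_hz, time_s = NULL, residual_px = NULL) {
  stopifnot(is.array(xyz), length(dim(xyz)) == 3L, dim(xyz)[3L] == 3L)
  if (!is.finite(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  time_s <- time_s %||% ((seq_len(dim(xyz)[1L]) - 1) / rate_hz)
  structure(
    list(xyz = xyz, rate_hz = rate_hz, time_s = as.numeric(time_s),
         residual_px = residual_px),
    class = "skeleton_series"
  )
}

#' @export
print.skeleton_series <- function(x, ...) {
  d <- dim(x$xyz)
  cat(sprintf("Skeleton series: %d frames x %d keypoints @ %g Hz\n",
              d[1], d[2], x$rate_hz))
  invisible(x)
}
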