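#' Observation noise model for a simulated session
#'
#' @param pixel_sd_px standard deviation (px) of i.i.d. Gaussian noise added
#'   to every 2D keypoint coordinate.
#' @param ref_sd_deg standard deviation (degrees) of the independent noise
#'   on the high-rate reference angle trace.
#' @param ref_offset_deg constant offset (degrees) added to the reference
#'   trace, emulating a systematic between-system discrepancy.
#' @param seed integer RNG seed; recorded in every output.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(pixel_sd_px = 1, ref_sd_deg = 1, seed = 42)
#' @export
noise_model <- function(pixel_sd_px = 1, ref_sd_deg = 1,
                        ref_offset_deg = 0, seed = 42) {
  if (pixel_sd_px < 0 || ref_sd_deg < 0) stopf("noise sigmas must be >= 0")
  if (!is.finite(seed)) stopf("seed must be a finite integer")
  structure(
    list(pixel_sd_px = pixel_sd_px, ref_sd_deg = ref_sd_deg,
         ref_offset_deg = ref_offset_deg, seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' 2D keypoint time series for one camera
#'
#' @param frame integer frame indices starting at 0.
#' @param time_s time stamps (s).
#' @param coords data.frame with `<keypoint>_x` / `<keypoint>_y` columns in
#'   pixels; `NA` marks a missing observation.
#' @param camera camera name.
#' @param rate_hz sample rate (Hz).
#' @return A data.frame of class `keypoint_series` with columns `frame`,
#'   `time_s`, then the coordinate columns; camera name and rate stored as
#'   attributes.
#' @export
keypoint_series <- function(frame, time_s, coords, camera, rate_hz) {
  out <- cbind(data.frame(frame = as.integer(frame), time_s = time_s),
               coords)
  attr(out, "camera") <- camera
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("keypoint_series", "data.frame")
  out
}

keypoint_names_of <- function(series) {
  nm <- names(series)
  sub("_x$", "", grep("_x$", nm, value = TRUE))
}

#' Project a skeleton through one camera with pixel noise
#'
#' Perspective-projects every keypoint of every frame and adds i.i.d.
#' Gaussian pixel noise. A keypoint is marked missing (`NA`) when it lies at
#' or behind the camera's optical centre, or when its noiseless projection
#' falls outside the image bounds; missing observations are never
#' fabricated.
#'
#' @param camera a [camera_model()].
#' @param skel a `skeleton_series` (see [forward_kinematics()]).
#' @param noise a [noise_model()]; only `pixel_sd_px` and `seed` are used.
#'   The draw is seeded, so identical inputs give identical output.
#' @return A [keypoint_series()].
#' @examples
#' skel <- forward_kinematics(skeleton_params(),
#'                            generate_angle_profile(motion_profile()))
#' kp <- project_with_noise(make_camera_ring(4)[[1]], skel,
#'                          noise_model(pixel_sd_px = 0))
#' head(kp[, 1:4])
#' @export
project_with_noise <- function(camera, skel, noise = noise_model()) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(skel, "skeleton_series"),
            inherits(noise, "noise_model"))
  kp <- dimnames(skel$xyz)[[2L]]
  n <- dim(skel$xyz)[1L]
  set.seed(noise$seed)
  cols <- vector("list", 2L * length(kp))
  names(cols) <- as.vector(rbind(paste0(kp, "_x"), paste0(kp, "_y")))
  w <- camera$image_size_px[1]
  h <- camera$image_size_px[2]
  for (j in seq_along(kp)) {
    uvz <- project_points(camera, skel$xyz[, j, , drop = TRUE])
    bad <- is.na(uvz[, "depth"]) | uvz[, "depth"] <= 1e-9 |
      uvz[, "u"] < 0 | uvz[, "u"] > w | uvz[, "v"] < 0 | uvz[, "v"] > h
    u <- uvz[, "u"] + stats::rnorm(n, 0, noise$pixel_sd_px)
    v <- uvz[, "v"] + stats::rnorm(n, 0, noise$pixel_sd_px)
    u[bad] <- NA_real_
    v[bad] <- NA_real_
    cols[[2L * j - 1L]] <- u
    cols[[2L * j]] <- v
  }
  keypoint_series(frame = seq_len(n) - 1L, time_s = skel$time_s,
                  coords = as.data.frame(cols), camera = camera$name,
                  rate_hz = skel$rate_hz)
}
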