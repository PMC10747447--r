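#' Triangulate one 3D point from calibrated 2D observations
#'
#' Direct linear transform: each view contributes two rows of a homogeneous
#' linear system in the unknown world point, solved by singular value
#' decomposition. Pixel coordinates are first normalised per view (shifted
#' by the principal point and scaled by the focal length), which conditions
#' the system independently of image resolution.
#'
#' @param observations list of `list(camera = <camera_model>, px = c(u, v))`
#'   entries; at least two views from cameras with distinct centres.
#' @return List with `point` (world 3-vector, m), `residual_px` (RMS
#'   reprojection error over the views), and `degenerate` (TRUE when the two
#'   smallest singular values are nearly equal, i.e. near-parallel rays make
#'   the solution ambiguous; the point is still returned).
#' @examples
#' rig <- make_camera_ring(4)
#' X <- c(0.1, -0.2, 1.1)
#' obs <- lapply(rig, function(cm) {
#'   list(camera = cm, px = project_points(cm, X)[1, 1:2])
#' })
#' triangulate_point(obs)$point
#' @export
triangulate_point <- function(observations) {
  observations <- Filter(function(o) !any(is.na(o$px)), observations)
  if (length(observations) < 2L) {
    stopf("insufficient views: triangulation needs >= 2 observations")
  }
  centers <- t(vapply(observations, function(o) camera_center(o$camera),
                      numeric(3L)))
  if (max(dist(centers)) < 1e-9) {
    stopf("triangulation needs cameras with distinct centres")
  }
  A <- matrix(0, 2L * length(observations), 4L)
  for (i in seq_along(observations)) {
    o <- observations[[i]]
    cam <- o$camera
    ## normalised image coordinates: unit focal, principal point at origin
    xn <- (o$px[1] - cam$principal_px[1]) / cam$focal_px[1]
    yn <- (o$px[2] - cam$principal_px[2]) / cam$focal_px[2]
    Pn <- cbind(cam$rotation, cam$translation)
    A[2L * i - 1L, ] <- xn * Pn[3L, ] - Pn[1L, ]
    A[2L * i, ] <- yn * Pn[3L, ] - Pn[2L, ]
  }
  sv <- svd(A)
  Xh <- sv$v[, 4L]
  degenerate <- sv$d[4L] > 0.9 * sv$d[3L]
  if (abs(Xh[4L]) < 1e-12) {
    return(list(point = rep(NA_real_, 3L), residual_px = NA_real_,
                degenerate = TRUE))
  }
  X <- Xh[1:3] / Xh[4L]
  err2 <- vapply(observations, function(o) {
    uv <- project_points(o$camera, X)[1L, 1:2]
    sum((uv - o$px)^2)
  }, numeric(1L))
  list(point = X,
       residual_px = sqrt(mean(err2)),
       degenerate = degenerate)
}

#' Triangulate a multi-view keypoint series to 3D
#'
#' Applies [triangulate_point()] frame by frame and keypoint by keypoint
#' across all camera views. Keypoints observed in fewer than `min_views`
#' cameras at a frame are marked missing rather than reconstructed.
#'
#' @param rig list of [camera_model()]s.
#' @param views list of [keypoint_series()], one per camera, on a shared
#'   frame grid; matched to rig cameras by name.
#' @param min_views minimum number of observing cameras (default 2).
#' @return A `skeleton_series` with per-keypoint RMS reprojection residuals
#'   in `residual_px`.
#' @examples
#' skel <- forward_kinematics(skeleton_params(),
#'                            generate_angle_profile(motion_profile()))
#' rig <- make_camera_ring(4)
#' views <- lapply(rig, project_with_noise, skel = skel,
#'                 noise = noise_model(pixel_sd_px = 0))
#' rec <- triangulate_series(rig, views)
#' max(abs(rec$xyz - skel$xyz))
#' @export
triangulate_series <- function(rig, views, min_views = 2L) {
  stopifnot(length(rig) >= 1L, length(views) >= 1L)
  rig_names <- vapply(rig, `[[`, character(1L), "name")
  view_names <- vapply(views, attr, character(1L), "camera")
  if (!all(view_names %in% rig_names)) {
    stopf("views reference cameras absent from the rig: %s",
          paste(setdiff(view_names, rig_names), collapse = ", "))
  }
  nf <- unique(vapply(views, nrow, integer(1L)))
  if (length(nf) != 1L) {
    stopf("all views must share one frame grid (got %s frames)",
          paste(sort(nf), collapse = ", "))
  }
  for (v in views[-1L]) {
    if (max(abs(v$time_s - views[[1L]]$time_s)) > 1e-9) {
      stopf("view time stamps disagree; views must share one frame grid")
    }
  }
  cams <- rig[match(view_names, rig_names)]
  kp <- Reduce(union, lapply(views, keypoint_names_of))
  xyz <- array(NA_real_, dim = c(nf, length(kp), 3L),
               dimnames = list(NULL, kp, c("x", "y", "z")))
  resid <- matrix(NA_real_, nf, length(kp), dimnames = list(NULL, kp))
  for (j in seq_along(kp)) {
    cx <- paste0(kp[j], "_x")
    cy <- paste0(kp[j], "_y")
    for (i in seq_len(nf)) {
      obs <- list()
      for (v in seq_along(views)) {
        if (!cx %in% names(views[[v]])) next
        px <- c(views[[v]][[cx]][i], views[[v]][[cy]][i])
        if (any(is.na(px))) next
        obs[[length(obs) + 1L]] <- list(camera = cams[[v]], px = px)
      }
      if (length(obs) < max(2L, min_views)) next
      tri <- triangulate_point(obs)
      xyz[i, j, ] <- tri$point
      resid[i, j] <- tri$residual_px
    }
  }
  skeleton_series(xyz, rate_hz = attr(views[[1L]], "rate_hz"),
                  time_s = views[[1L]]$time_s, residual_px = resid)
}
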