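#' Pinhole camera model
#'
#' Intrinsic and extrinsic parameters of one calibrated camera. World points
#' `X` map to camera coordinates `R X + t` and on to pixels through the
#' intrinsic matrix; the pixel origin is the top-left image corner with x
#' right and y down.
#'
#' @param name camera identifier.
#' @param focal_px focal length in pixels; length 1 (isotropic) or 2
#'   `(fx, fy)`.
#' @param principal_px principal point `(cx, cy)` in pixels; must fall
#'   inside the image.
#' @param image_size_px image `(width, height)` in pixels.
#' @param rotation 3x3 world-to-camera rotation; orthonormal with
#'   determinant +1 (checked to 1e-9).
#' @param translation length-3 translation (camera frame).
#' @return An object of class `camera_model`.
#' @examples
#' camera_model("cam0", 900, c(960, 540), c(1920, 1080), diag(3), c(0, 0, 3))
#' @export
camera_model <- function(name, focal_px, principal_px, image_size_px,
                         rotation, translation) {
  focal_px <- rep_len(as.numeric(focal_px), 2L)
  if (any(!is.finite(focal_px)) || any(focal_px <= 0)) {
    stopf("focal_px must be > 0")
  }
  principal_px <- as.numeric(principal_px)
  image_size_px <- as.numeric(image_size_px)
  if (length(principal_px) != 2L || length(image_size_px) != 2L) {
    stopf("principal_px and image_size_px must have length 2")
  }
  if (any(principal_px < 0) || any(principal_px > image_size_px)) {
    stopf("principal point must lie within the image bounds")
  }
  rotation <- as.matrix(rotation)
  check_rotation(rotation)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stopf("translation must be a finite 3-vector")
  }
  structure(
    list(name = as.character(name), focal_px = focal_px,
         principal_px = principal_px, image_size_px = image_size_px,
         rotation = rotation, translation = translation),
    class = "camera_model"
  )
}

check_rotation <- function(R, tol = 1e-9) {
  if (!all(dim(R) == c(3L, 3L)) || any(!is.finite(R))) {
    stopf("rotation must be a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stopf("rotation is not orthonormal (tolerance %g)", tol)
  }
  if (abs(det(R) - 1) > tol) {
    stopf("rotation must have determinant +1 (got %g)", det(R))
  }
  invisible(R)
}

#' Intrinsic matrix of a camera
#' @param camera a [camera_model()].
#' @return 3x3 upper-triangular intrinsic matrix.
#' @export
intrinsic_matrix <- function(camera) {
  matrix(c(camera$focal_px[1], 0, camera$principal_px[1],
           0, camera$focal_px[2], camera$principal_px[2],
           0, 0, 1), nrow = 3L, byrow = TRUE)
}

#' 3x4 projection matrix of a camera
#'
#' Composes intrinsics and extrinsics: `P = K [R | t]`. Projecting a
#' homogeneous world point `X` gives the pixel as the dehomogenised `P X`.
#'
#' @param camera a [camera_model()].
#' @return 3x4 numeric projection matrix.
#' @examples
#' cam <- camera_model("c", 1, c(0, 0), c(2, 2), diag(3), c(0, 0, 0))
#' projection_matrix(cam) %*% c(0, 0, 5, 1) # on-axis point -> principal point
#' @export
projection_matrix <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  intrinsic_matrix(camera) %*% cbind(camera$rotation, camera$translation)
}

#' Optical centre of a camera in world coordinates
#' @param camera a [camera_model()].
#' @return length-3 world position (m).
#' @export
camera_center <- function(camera) {
  as.numeric(-crossprod(camera$rotation, camera$translation))
}

#' Evenly spaced ring of cameras
#'
#' Places `n` cameras on a horizontal circle around the capture volume, all
#' aimed at `target`. Emulates a multi-view RGB capture rig surrounding a
#' standing subject.
#'
#' @param n number of cameras (>= 2; at least two views are required for
#'   triangulation).
#' @param radius_m ring radius (m).
#' @param height_m camera height above the floor (m).
#' @param focal_px focal length (px).
#' @param image_size_px image `(width, height)` (px).
#' @param target world point every camera looks at (m).
#' @return List of [camera_model()]s named `cam1 ... camN`.
#' @examples
#' rig <- make_camera_ring(4)
#' length(rig)
#' @export
make_camera_ring <- function(n = 4, radius_m = 3, height_m = 1.2,
                             focal_px = 900, image_size_px = c(1920, 1080),
                             target = c(0, 0, 0.9)) {
  if (!is.finite(n) || n < 2) {
    stopf("at least 2 cameras are required for triangulation")
  }
  n <- as.integer(n)
  if (radius_m <= 0) stopf("radius_m must be > 0")
  lapply(seq_len(n), function(i) {
    az <- 2 * pi * (i - 1) / n
    center <- c(radius_m * cos(az), radius_m * sin(az), height_m)
    R <- look_at_rotation(center, target)
    camera_model(
      name = sprintf("cam%d", i),
      focal_px = focal_px,
      principal_px = image_size_px / 2,
      image_size_px = image_size_px,
      rotation = R,
      translation = as.numeric(-R %*% center)
    )
  })
}

## World->camera rotation for a camera at `center` looking at `target`,
## with the image x axis horizontal and y pointing down in the world.
look_at_rotation <- function(center, target, up = c(0, 0, 1)) {
  z <- unit_vector(target - center, "viewing direction")
  x <- cross3(z, up)
  if (vnorm(x) < 1e-9) { # looking straight up/down: pick any horizontal x
    x <- cross3(z, c(0, 1, 0))
  }
  x <- unit_vector(x)
  y <- cross3(z, x)
  rbind(x, y, z, deparse.level = 0)
}

## Project an n x 3 matrix of world points through one camera.
## Returns n x 3: pixel u, v and camera-frame depth.
project_points <- function(camera, X) {
  X <- matrix(X, ncol = 3L)
  Xc <- X %*% t(camera$rotation) +
    matrix(camera$translation, nrow(X), 3L, byrow = TRUE)
  z <- Xc[, 3L]
  u <- camera$focal_px[1] * Xc[, 1L] / z + camera$principal_px[1]
  v <- camera$focal_px[2] * Xc[, 2L] / z + camera$principal_px[2]
  cbind(u = u, v = v, depth = z)
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera '%s': f=(%g, %g) px, image %gx%g, centre (%s) m\n",
              x$name, x$focal_px[1], x$focal_px[2],
              x$image_size_px[1], x$image_size_px[2],
              paste(signif(camera_center(x), 4), collapse = ", ")))
  invisible(x)
}
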