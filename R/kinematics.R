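#' Torso coordinate frame from four keypoints
#'
#' Builds the anatomical torso frame used for hip angles. The Z axis points
#' from the hip joint in use to the neck; the X axis is normal to the plane
#' spanned by the two shoulders and that hip, oriented by the cross product
#' of the left-shoulder and right-shoulder vectors taken in that order; Y
#' completes the right-handed triad (`Y = Z x X`).
#'
#' @param neck,shoulder_L,shoulder_R,hip world 3-vectors (m).
#' @return List of class `torso_frame` with unit axes `X`, `Y`, `Z` and
#'   `origin` (the hip).
#' @examples
#' torso_frame(c(0, 0, 1), c(0.2, 0, 0.9), c(-0.2, 0, 0.9), c(0, 0, 0))
#' @export
torso_frame <- function(neck, shoulder_L, shoulder_R, hip) {
  neck <- as.numeric(neck)
  shoulder_L <- as.numeric(shoulder_L)
  shoulder_R <- as.numeric(shoulder_R)
  hip <- as.numeric(hip)
  Z <- unit_vector(neck - hip, "torso axis (neck coincides with hip?)")
  nrm <- cross3(shoulder_L - hip, shoulder_R - hip)
  if (vnorm(nrm) < 1e-12) {
    stopf("degenerate torso frame: shoulders and hip are collinear")
  }
  X <- unit_vector(nrm)
  if (abs(sum(X * Z)) > 1 - 1e-9) {
    stopf("degenerate torso frame: shoulder plane normal parallel to torso axis")
  }
  ## re-orthogonalise X against Z so the triad is exactly orthonormal even
  ## for slightly asymmetric shoulder placements
  X <- unit_vector(X - sum(X * Z) * Z)
  Y <- cross3(Z, X)
  structure(list(X = X, Y = Y, Z = Z, origin = hip), class = "torso_frame")
}

#' Hip flexion/extension angle
#'
#' Angle between the negative torso Z axis and the femur axis (hip to
#' knee), in degrees. This quantifies hip flexion in 3D regardless of the
#' plane the thigh moves in: 0 degrees in the anatomically neutral standing
#' pose (femur antiparallel to the torso axis) up to 180 degrees with the
#' thigh fully raised along the torso axis.
#'
#' @param frame a [torso_frame()].
#' @param hip,knee world 3-vectors (m).
#' @return Angle in degrees in \[0, 180\].
#' @examples
#' fr <- torso_frame(c(0, 0, 1), c(0.2, 0, 0.9), c(-0.2, 0, 0.9), c(0, 0, 0))
#' hip_flexion_angle(fr, c(0, 0, 0), c(0, 0, -0.45)) # neutral: 0
#' @export
hip_flexion_angle <- function(frame, hip, knee) {
  stopifnot(inherits(frame, "torso_frame"))
  femur <- unit_vector(knee - hip, "femur axis")
  angle_between(-frame$Z, femur)
}

## Angle between two unit vectors in degrees. Equivalent to the arccos of
## the clamped dot product but evaluated through atan2, which keeps full
## precision near 0 and 180 degrees.
angle_between <- function(a, b) {
  rad2deg(atan2(vnorm(cross3(a, b)), clamp_unit(sum(a * b))))
}

#' Knee flexion angle
#'
#' Angle between the femur axis (hip to knee) and the tibia axis (knee to
#' ankle): 0 degrees with the knee fully extended (axes parallel), 180 with
#' the shank folded back onto the thigh.
#'
#' @param hip,knee,ankle world 3-vectors (m).
#' @return Angle in degrees in \[0, 180\].
#' @examples
#' knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5), c(0, 0, 0)) # extended: 0
#' @export
knee_flexion_angle <- function(hip, knee, ankle) {
  femur <- unit_vector(knee - hip, "femur axis")
  tibia <- unit_vector(ankle - knee, "tibia axis")
  angle_between(femur, tibia)
}

#' Signed trunk side-bending angle
#'
#' Elevation angle of the shoulder line (right shoulder to left shoulder)
#' relative to the floor plane Z = 0: positive when the left shoulder is
#' lower than the right (side bend to the left), negative on the other
#' side.
#'
#' @param shoulder_L,shoulder_R world 3-vectors (m).
#' @return Signed angle in degrees in (-90, 90).
#' @examples
#' trunk_side_bend_angle(c(0, 0.1732, 0.9), c(0, -0.1732, 1.0)) # +30
#' @export
trunk_side_bend_angle <- function(shoulder_L, shoulder_R) {
  d <- as.numeric(shoulder_L) - as.numeric(shoulder_R)
  horiz <- sqrt(d[1L]^2 + d[2L]^2)
  if (horiz < 1e-12) {
    stopf("degenerate shoulder line: no horizontal extent")
  }
  rad2deg(atan2(-d[3L], horiz))
}

required_keypoints <- function(task) {
  switch(task_family(task),
         side_dip = c("shoulder_L", "shoulder_R"),
         ybt = c("neck", "shoulder_L", "shoulder_R", "hip_R", "knee_R"))
}

#' Extract the task's joint-angle trace from a 3D skeleton series
#'
#' Dispatches per task: side dips yield the signed trunk side-bending angle
#' (left positive); the Y-balance reach yields the unsigned hip angle of
#' the right (moving) leg, computed against the torso frame anchored at the
#' right hip. Frames with a missing required keypoint yield a missing
#' sample; the trace continues.
#'
#' @param skel a `skeleton_series`.
#' @param task task kind.
#' @return An [angle_trace()] at the skeleton's sample rate.
#' @examples
#' sk <- forward_kinematics(skeleton_params(),
#'                          generate_angle_profile(motion_profile()))
#' tr <- angle_trace_from_skeleton(sk, "side_dip_left")
#' max(tr$angle_deg)
#' @export
angle_trace_from_skeleton <- function(skel,
                                      task = c("side_dip_left",
                                               "side_dip_right",
                                               "ybt_hip_extension")) {
  stopifnot(inherits(skel, "skeleton_series"))
  task <- match.arg(task)
  need <- required_keypoints(task)
  have <- dimnames(skel$xyz)[[2L]]
  if (length(setdiff(need, have))) {
    stopf("skeleton series lacks required keypoints: %s",
          paste(setdiff(need, have), collapse = ", "))
  }
  n <- dim(skel$xyz)[1L]
  ang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    P <- skel$xyz[i, , ]
    if (any(is.na(P[need, ]))) next
    ang[i] <- if (task_family(task) == "side_dip") {
      trunk_side_bend_angle(P["shoulder_L", ], P["shoulder_R", ])
    } else {
      fr <- torso_frame(P["neck", ], P["shoulder_L", ], P["shoulder_R", ],
                        P["hip_R", ])
      hip_flexion_angle(fr, P["hip_R", ], P["knee_R", ])
    }
  }
  angle_trace(ang, rate_hz = skel$rate_hz, task = task, time_s = skel$time_s)
}
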