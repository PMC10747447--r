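#' Minimal seven-keypoint skeleton parameters
#'
#' Segment lengths (metres) of the reduced body model used by the synthetic
#' session generator: a torso from the hip line to the neck, a shoulder line,
#' and a right leg (femur + tibia). Seven named keypoints are tracked: neck,
#' both shoulders, both hips, right knee and right ankle.
#'
#' @param torso_m hip-to-neck length (m).
#' @param shoulder_halfwidth_m half distance between the shoulders (m).
#' @param femur_m hip-to-knee length (m).
#' @param tibia_m knee-to-ankle length (m).
#' @param hip_halfwidth_m half distance between the hip joints (m).
#' @param root world position (m) of the hip-line midpoint in the neutral
#'   standing pose; the default stands the ankle on the floor plane Z = 0.
#' @param keypoints character vector of tracked keypoint names; must contain
#'   the seven canonical names in [mvk_keypoints()].
#' @return An object of class `skeleton_params`.
#' @examples
#' skeleton_params()
#' @export
skeleton_params <- function(torso_m = 0.50,
                            shoulder_halfwidth_m = 0.20,
                            femur_m = 0.45,
                            tibia_m = 0.43,
                            hip_halfwidth_m = 0.10,
                            root = c(0, 0, femur_m + tibia_m),
                            keypoints = mvk_keypoints()) {
  lens <- c(torso_m = torso_m, shoulder_halfwidth_m = shoulder_halfwidth_m,
            femur_m = femur_m, tibia_m = tibia_m,
            hip_halfwidth_m = hip_halfwidth_m)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stopf("all segment lengths must be finite and > 0")
  }
  if (length(root) != 3L || any(!is.finite(root))) {
    stopf("root must be a finite 3-vector")
  }
  missing_kp <- setdiff(mvk_keypoints(), keypoints)
  if (length(missing_kp)) {
    stopf("keypoint set is missing: %s", paste(missing_kp, collapse = ", "))
  }
  structure(
    list(torso_m = torso_m,
         shoulder_halfwidth_m = shoulder_halfwidth_m,
         femur_m = femur_m,
         tibia_m = tibia_m,
         hip_halfwidth_m = hip_halfwidth_m,
         root = as.numeric(root),
         keypoints = keypoints),
    class = "skeleton_params"
  )
}

#' Canonical keypoint names
#'
#' The seven body keypoints tracked by the pipeline.
#'
#' @return Character vector of keypoint names.
#' @export
mvk_keypoints <- function() {
  c("neck", "shoulder_L", "shoulder_R", "hip_R", "hip_L", "knee_R", "ankle_R")
}

#' @export
print.skeleton_params <- function(x, ...) {
  cat("Skeleton parameters (m): torso", x$torso_m,
      "| shoulder half-width", x$shoulder_halfwidth_m,
      "| femur", x$femur_m, "| tibia", x$tibia_m, "\n")
  cat("Root:", paste(signif(x$root, 4), collapse = ", "),
      "| keypoints:", length(x$keypoints), "\n")
  invisible(x)
}
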