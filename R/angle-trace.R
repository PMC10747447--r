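#' Joint-angle trace
#'
#' A sampled joint-angle signal in degrees together with its sample rate,
#' the task it was recorded from, and its sign convention. Trunk
#' side-bending traces are signed (`left_positive`: positive when bending to
#' the subject's left); hip/knee angles are unsigned in \[0, 180\].
#'
#' @param angle_deg numeric vector of angles in degrees (`NA` = missing).
#' @param rate_hz sample rate in Hz.
#' @param task one of `"side_dip_left"`, `"side_dip_right"`,
#'   `"ybt_hip_extension"`.
#' @param convention sign convention tag: `"left_positive"`,
#'   `"right_positive"` or `"unsigned_0_180"`.
#' @param time_s optional explicit time stamps (s); defaults to a uniform
#'   grid at `rate_hz` starting at 0.
#' @return An object of class `angle_trace`.
#' @examples
#' angle_trace(c(0, 10, 20, 10, 0), rate_hz = 12, task = "side_dip_left")
#' @export
angle_trace <- function(angle_deg, rate_hz,
                        task = c("side_dip_left", "side_dip_right",
                                 "ybt_hip_extension"),
                        convention = NULL,
                        time_s = NULL) {
  task <- match.arg(task)
  if (!is.numeric(angle_deg) || length(angle_deg) < 1L) {
    stopf("angle_deg must be a non-empty numeric vector")
  }
  if (!is.finite(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  convention <- convention %||% default_convention(task)
  convention <- match.arg(convention,
                          c("left_positive", "right_positive",
                            "unsigned_0_180"))
  ok <- !is.na(angle_deg)
  if (convention == "unsigned_0_180") {
    if (any(angle_deg[ok] < -1e-9 | angle_deg[ok] > 180 + 1e-9)) {
      stopf("unsigned angles must lie in [0, 180] degrees")
    }
  } else if (any(abs(angle_deg[ok]) > 180 + 1e-9)) {
    stopf("signed angles must lie in [-180, 180] degrees")
  }
  time_s <- time_s %||% (seq_along(angle_deg) - 1) / rate_hz
  if (length(time_s) != length(angle_deg)) {
    stopf("time_s and angle_deg lengths differ")
  }
  structure(
    list(angle_deg = as.numeric(angle_deg),
         time_s = as.numeric(time_s),
         rate_hz = rate_hz,
         task = task,
         convention = convention),
    class = "angle_trace"
  )
}

default_convention <- function(task) {
  if (task == "ybt_hip_extension") "unsigned_0_180" else "left_positive"
}

task_family <- function(task) {
  if (task %in% c("side_dip_left", "side_dip_right")) "side_dip" else "ybt"
}

#' @export
length.angle_trace <- function(x) length(x$angle_deg)

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("Angle trace: %s | %d samples @ %g Hz | %s\n",
              x$task, length(x$angle_deg), x$rate_hz, x$convention))
  rng <- range(x$angle_deg, na.rm = TRUE)
  cat(sprintf("  range [%.2f, %.2f] deg, %d missing\n",
              rng[1], rng[2], sum(is.na(x$angle_deg))))
  invisible(x)
}
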