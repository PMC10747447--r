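#' Locate the max--min section of a trial
#'
#' Finds the section of a trial spanned by the global maximum and global
#' minimum of a representative indicator trace, in time order (earlier
#' extremum first, ties broken by the earliest index). The window, expressed
#' in normalised time, is what the pairing procedure keeps from each
#' system's recording.
#'
#' @param trace the [angle_trace()] the window will be applied to; must
#'   share the representative's time base.
#' @param representative the indicator trace that defines the extremes;
#'   defaults to `trace` itself.
#' @return List of class `section_window`: `start`, `end` (0-based frame
#'   indices into the representative), `max_deg`, `min_deg`,
#'   `max_first` (logical: does the maximum precede the minimum?).
#' @examples
#' tr <- angle_trace(c(0, 1, 2, 3, 2, 1), 12, "side_dip_left")
#' extract_section(tr)
#' @export
extract_section <- function(trace, representative = trace) {
  stopifnot(inherits(trace, "angle_trace"),
            inherits(representative, "angle_trace"))
  a <- representative$angle_deg
  if (length(a) < 2L) stopf("representative trace needs >= 2 samples")
  if (all(is.na(a))) stopf("representative trace is all missing")
  i_max <- which.max(a)
  i_min <- which.min(a)
  if (a[i_max] == a[i_min]) {
    stopf("no motion: representative trace is constant")
  }
  structure(
    list(start = min(i_max, i_min) - 1L,
         end = max(i_max, i_min) - 1L,
         max_deg = a[i_max], min_deg = a[i_min],
         max_first = i_max < i_min),
    class = "section_window"
  )
}

apply_section <- function(trace, window) {
  idx <- (window$start + 1L):(window$end + 1L)
  angle_trace(trace$angle_deg[idx], rate_hz = trace$rate_hz,
              task = trace$task, convention = trace$convention,
              time_s = trace$time_s[idx])
}

#' Resample an angle trace to a fixed number of frames
#'
#' Linear interpolation onto `n` points evenly spaced over the trace's
#' normalised time \[0, 1\]. The first and last samples are preserved
#' exactly, interior missing samples are linearly bridged (with a warning),
#' and resampling an n-sample trace to the same n reproduces it bit for
#' bit.
#'
#' @param trace an [angle_trace()] with at least 2 samples.
#' @param n number of output frames (default 100).
#' @return An [angle_trace()] of length `n`; its nominal rate is scaled so
#'   the duration is unchanged.
#' @examples
#' resample_to_n(angle_trace(c(0, 1, 2), 12, "side_dip_left"), 5)$angle_deg
#' @export
resample_to_n <- function(trace, n = 100L) {
  stopifnot(inherits(trace, "angle_trace"))
  a <- trace$angle_deg
  m <- length(a)
  if (m < 2L) stopf("trace needs >= 2 samples to resample")
  if (n < 2L) stopf("n must be >= 2")
  ok <- !is.na(a)
  if (!any(ok)) stopf("trace is all missing; cannot resample")
  if (is.na(a[1L]) || is.na(a[m])) {
    stopf("trace endpoints are missing; trim the trial before resampling")
  }
  tt <- (seq_len(m) - 1) / (m - 1)
  if (any(!ok)) {
    warning("bridging ", sum(!ok), " interior missing sample(s) linearly",
            call. = FALSE)
  }
  grid <- (seq_len(n) - 1) / (n - 1)
  out <- stats::approx(tt[ok], a[ok], xout = grid, method = "linear",
                       ties = "ordered")$y
  ## duration preserved: n samples over the same span
  dur <- (m - 1) / trace$rate_hz
  angle_trace(out, rate_hz = (n - 1) / dur, task = trace$task,
              convention = trace$convention, time_s = grid * dur)
}

#' Harmonise the sign conventions of a trace pair
#'
#' The two systems may report the same signed angle under opposite sign
#' conventions (e.g. the reference system counts a right side bend as
#' positive). When the conventions differ, the reference trace is negated
#' and retagged to the test trace's convention; unsigned conventions pass
#' through unchanged.
#'
#' @param test,reference [angle_trace()]s of the same task family.
#' @return List with elements `test` and `reference`.
#' @export
harmonize_signs <- function(test, reference) {
  stopifnot(inherits(test, "angle_trace"), inherits(reference, "angle_trace"))
  if (task_family(test$task) != task_family(reference$task)) {
    stopf("task mismatch: cannot pair %s with %s", test$task, reference$task)
  }
  if (test$convention != reference$convention &&
      test$convention != "unsigned_0_180" &&
      reference$convention != "unsigned_0_180") {
    reference <- angle_trace(-reference$angle_deg,
                             rate_hz = reference$rate_hz,
                             task = reference$task,
                             convention = test$convention,
                             time_s = reference$time_s)
  }
  list(test = test, reference = reference)
}

#' Pair a test trace with a reference trace on a 100-frame grid
#'
#' The pairing procedure applied to every trial: cut each system's
#' recording to its own max--min section, resample both sections to a
#' common `n`-frame grid over normalised time, and harmonise sign
#' conventions. When the two sections run in opposite directions (one from
#' minimum to maximum, the other from maximum to minimum -- which happens
#' when sensor noise relocates an extremum between a trial's flat start and
#' end), the reference section is reversed in time so that like extremes
#' are paired, mirroring the visual matching of recordings that share a
#' capture window.
#'
#' @param test low-rate test-system trace.
#' @param reference high-rate reference-system trace.
#' @param n frames in the common grid (default 100).
#' @param window_from `"test"` (default): the test trace is the single
#'   representative indicator and its max--min window, expressed in
#'   normalised time, is applied to both recordings -- valid whenever the
#'   two systems capture the same trial span, as when they are started and
#'   stopped together. `"each"`: each recording is cut at its own extremes,
#'   for recordings that do not share a time base; sensor noise can then
#'   relocate an extremum between a trial's flat start and end, so when the
#'   two sections run in opposite directions the reference section is
#'   reversed in time so that like extremes are paired.
#' @param provenance optional named list (participant, task, side, ...)
#'   carried through to reports.
#' @return Object of class `aligned_pair`: `test` and `reference` numeric
#'   vectors of length `n`, `grid` (normalised time), `convention`, `task`,
#'   `windows` (the [extract_section()] results used) and `provenance`.
#' @examples
#' prof <- motion_profile("side_dip_left")
#' lo <- generate_angle_profile(prof)            # 12 Hz
#' hi <- generate_angle_profile(prof, rate_hz = 100)
#' pr <- pair_traces(lo, hi)
#' max(abs(pr$test - pr$reference)) < 0.05
#' @export
pair_traces <- function(test, reference, n = 100L,
                        window_from = c("test", "each"),
                        provenance = list()) {
  window_from <- match.arg(window_from)
  hs <- harmonize_signs(test, reference)
  test <- hs$test
  reference <- hs$reference
  w_test <- extract_section(test)
  cut_test <- resample_to_n(apply_section(test, w_test), n)
  if (window_from == "test") {
    rr <- range(reference$angle_deg, na.rm = TRUE)
    if (rr[1] == rr[2]) stopf("no motion: reference trace is constant")
    ## shared capture span: reuse the representative's window fractions
    m <- length(test$angle_deg)
    a <- w_test$start / (m - 1)
    b <- w_test$end / (m - 1)
    grid_n <- (seq_len(n) - 1) / (n - 1)
    ref_vals <- interp_normalized(reference, a + (b - a) * grid_n)
    w_ref <- w_test
  } else {
    w_ref <- extract_section(reference)
    cut_ref <- resample_to_n(apply_section(reference, w_ref), n)
    ref_vals <- cut_ref$angle_deg
    if (w_test$max_first != w_ref$max_first) {
      ref_vals <- rev(ref_vals)
    }
  }
  structure(
    list(test = cut_test$angle_deg,
         reference = ref_vals,
         grid = (seq_len(n) - 1) / (n - 1),
         task = test$task,
         convention = test$convention,
         windows = list(test = w_test, reference = w_ref),
         source_rates_hz = c(test = test$rate_hz,
                             reference = reference$rate_hz),
         provenance = provenance),
    class = "aligned_pair"
  )
}

## Linear interpolation of a trace at arbitrary normalised times in [0, 1].
interp_normalized <- function(trace, t_norm) {
  a <- trace$angle_deg
  ok <- !is.na(a)
  tt <- (seq_along(a) - 1) / (length(a) - 1)
  stats::approx(tt[ok], a[ok], xout = t_norm, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("Aligned pair: %s, %d frames, convention %s\n",
              x$task, length(x$test), x$convention))
  invisible(x)
}
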