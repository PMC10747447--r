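#' Simulation configuration for a paired capture session
#'
#' Assembles and validates the configuration of a synthetic
#' concurrent-validity session: one task repeated several times, watched by
#' a camera ring at a low frame rate while a reference system records the
#' same ground-truth angle at a high rate with independent noise. Defaults
#' reproduce the package's standard study conditions: a 40-degree
#' raised-cosine side dip over 5 s at 12 Hz, four cameras on a 3 m ring,
#' 1 px keypoint noise, a 100 Hz reference with 1 degree noise, five
#' repetitions.
#'
#' @param task task kind (see [motion_profile()]).
#' @param seed integer master seed; every repetition and camera derives its
#'   own sub-seed from it.
#' @param peak_deg,duration_s,rate_hz,hold_fraction motion profile.
#' @param repetitions number of repetitions of the motion.
#' @param pixel_sd_px 2D keypoint noise (px).
#' @param reference list: `rate_hz`, `sd_deg`, `offset_deg` of the
#'   reference system.
#' @param cameras list: `n`, `radius_m`, `height_m`, `focal_px`,
#'   `image_width_px`, `image_height_px`.
#' @param skeleton list of [skeleton_params()] arguments.
#' @return Object of class `sim_config` (a validated named list).
#' @examples
#' sim_config(seed = 42)
#' @export
sim_config <- function(task = "side_dip_left", seed = 42,
                       peak_deg = 40, duration_s = 5, rate_hz = 12,
                       hold_fraction = 0.2, repetitions = 5,
                       pixel_sd_px = 1,
                       reference = list(),
                       cameras = list(),
                       skeleton = list()) {
  cfg <- list(
    task = task, seed = seed, peak_deg = peak_deg, duration_s = duration_s,
    rate_hz = rate_hz, hold_fraction = hold_fraction,
    repetitions = repetitions, pixel_sd_px = pixel_sd_px,
    reference = utils::modifyList(
      list(rate_hz = 100, sd_deg = 1, offset_deg = 0), reference),
    cameras = utils::modifyList(
      list(n = 4, radius_m = 3, height_m = 1.2, focal_px = 900,
           image_width_px = 1920, image_height_px = 1080), cameras),
    skeleton = skeleton
  )
  validate_sim_config(cfg)
}

config_schema <- function() {
  list(
    top = c("task", "seed", "peak_deg", "duration_s", "rate_hz",
            "hold_fraction", "repetitions", "pixel_sd_px", "reference",
            "cameras", "skeleton"),
    required = c("task", "seed"),
    reference = c("rate_hz", "sd_deg", "offset_deg"),
    cameras = c("n", "radius_m", "height_m", "focal_px", "image_width_px",
                "image_height_px"),
    skeleton = c("torso_m", "shoulder_halfwidth_m", "femur_m", "tibia_m",
                 "hip_halfwidth_m")
  )
}

#' Validate a simulation configuration
#'
#' Checks a configuration list against the documented schema: required keys
#' present, no unknown keys, values in range.
#'
#' @param cfg named list (e.g. parsed from YAML/JSON).
#' @return The validated configuration, classed `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  sch <- config_schema()
  unknown <- setdiff(names(cfg), sch$top)
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(sch$required, names(cfg))
  if (length(missing)) {
    stopf("missing required configuration key(s): %s",
          paste(missing, collapse = ", "))
  }
  for (grp in c("reference", "cameras", "skeleton")) {
    bad <- setdiff(names(cfg[[grp]]), sch[[grp]])
    if (length(bad)) {
      stopf("unknown %s configuration key(s): %s", grp,
            paste(bad, collapse = ", "))
    }
  }
  if (!cfg$task %in% c("side_dip_left", "side_dip_right",
                       "ybt_hip_extension")) {
    stopf("unknown task: %s", cfg$task)
  }
  if (!is.finite(cfg$seed)) stopf("seed must be a finite integer")
  reps <- cfg$repetitions %||% 1
  if (!is.finite(reps) || reps < 1) stopf("repetitions must be >= 1")
  ## fill documented defaults; motion/noise parameters are range-checked by
  ## their constructors
  defaults <- list(peak_deg = 40, duration_s = 5, rate_hz = 12,
                   hold_fraction = 0.2, repetitions = 5, pixel_sd_px = 1,
                   reference = list(rate_hz = 100, sd_deg = 1,
                                    offset_deg = 0),
                   cameras = list(n = 4, radius_m = 3, height_m = 1.2,
                                  focal_px = 900, image_width_px = 1920,
                                  image_height_px = 1080),
                   skeleton = list())
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg[c(sch$required, setdiff(sch$top, sch$required))],
            class = "sim_config")
}

#' Read / write a simulation configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), decided by the file extension.
#' Configurations round-trip unchanged.
#'
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yml = ,
                yaml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stopf("unsupported config format: .%s", ext))
  validate_sim_config(cfg)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  cfg <- validate_sim_config(unclass(cfg))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(unclass(cfg), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopf("unsupported config format: .%s", ext)
  }
  invisible(path)
}

#' Simulate a paired markerless/reference capture session
#'
#' Generates `repetitions` independent repetitions of the configured
#' motion. Each repetition contains the ground-truth angle trace at the
#' camera rate and at the reference rate, noisy per-camera 2D keypoint
#' series from the ring, and the reference-system trace (ground truth plus
#' independent Gaussian noise plus a constant offset). All randomness
#' derives deterministically from the master seed, so identical
#' configurations give bit-identical sessions.
#'
#' @param config a [sim_config()] (or plain list validated against the
#'   schema).
#' @return List of class `session_set`; each element is a `session_bundle`
#'   with `truth`, `truth_ref_rate`, `views`, `reference`, `rig`,
#'   `skeleton`, `noise`, `profile`, `repetition`.
#' @examples
#' ses <- simulate_paired_session(sim_config(seed = 1, repetitions = 1))
#' length(ses)
#' @export
simulate_paired_session <- function(config = sim_config()) {
  cfg <- validate_sim_config(unclass(config))
  profile <- motion_profile(cfg$task, peak_deg = cfg$peak_deg %||% 40,
                            duration_s = cfg$duration_s %||% 5,
                            rate_hz = cfg$rate_hz %||% 12,
                            hold_fraction = cfg$hold_fraction %||% 0.2)
  params <- do.call(skeleton_params, cfg$skeleton %||% list())
  cam <- cfg$cameras
  rig <- make_camera_ring(n = cam$n, radius_m = cam$radius_m,
                          height_m = cam$height_m, focal_px = cam$focal_px,
                          image_size_px = c(cam$image_width_px,
                                            cam$image_height_px),
                          target = params$root)
  reps <- as.integer(cfg$repetitions %||% 1)
  truth <- generate_angle_profile(profile)
  truth_ref <- generate_angle_profile(profile,
                                      rate_hz = cfg$reference$rate_hz)
  skel <- forward_kinematics(params, truth)
  bundles <- lapply(seq_len(reps), function(r) {
    views <- lapply(seq_along(rig), function(ci) {
      project_with_noise(rig[[ci]], skel,
                         noise_model(pixel_sd_px = cfg$pixel_sd_px,
                                     seed = derive_seed(cfg$seed, r, ci)))
    })
    ref_seed <- derive_seed(cfg$seed, r, 9973L)
    set.seed(ref_seed)
    ref_vals <- truth_ref$angle_deg +
      stats::rnorm(length(truth_ref$angle_deg), 0, cfg$reference$sd_deg) +
      cfg$reference$offset_deg
    reference <- angle_trace(ref_vals, rate_hz = cfg$reference$rate_hz,
                             task = cfg$task, time_s = truth_ref$time_s)
    structure(
      list(truth = truth, truth_ref_rate = truth_ref, views = views,
           reference = reference, rig = rig, skeleton = params,
           noise = noise_model(pixel_sd_px = cfg$pixel_sd_px,
                               ref_sd_deg = cfg$reference$sd_deg,
                               ref_offset_deg = cfg$reference$offset_deg,
                               seed = derive_seed(cfg$seed, r)),
           profile = profile, repetition = r, config = cfg),
      class = "session_bundle"
    )
  })
  structure(bundles, class = "session_set", config = cfg)
}

#' Run the analysis pipeline on one simulated or loaded repetition
#'
#' Triangulates the per-camera keypoint series to 3D, extracts the task's
#' joint-angle trace, and pairs it with the reference trace on the
#' `n_frames` grid.
#'
#' @param bundle a `session_bundle` from [simulate_paired_session()] (or an
#'   equivalent list with `views`, `rig`, `reference` and `config`).
#' @param n_frames frames in the normalised grid (default 100).
#' @param min_views minimum cameras per reconstructed keypoint.
#' @return List with `skeleton` (triangulated `skeleton_series`), `trace`
#'   (markerless [angle_trace()]) and `pair` (the `aligned_pair`).
#' @export
analyze_session <- function(bundle, n_frames = 100L, min_views = 2L) {
  skel <- triangulate_series(bundle$rig, bundle$views, min_views = min_views)
  task <- bundle$config$task %||% bundle$reference$task
  trace <- angle_trace_from_skeleton(skel, task)
  prov <- list(task = task, repetition = bundle$repetition %||% NA)
  pair <- pair_traces(trace, bundle$reference, n = n_frames,
                      provenance = prov)
  list(skeleton = skel, trace = trace, pair = pair)
}

#' Simulate and analyse a full session, returning the agreement report
#'
#' Convenience wrapper chaining [simulate_paired_session()],
#' [analyze_session()] and [reliability_report()]: one report row per
#' repetition.
#'
#' @param config a [sim_config()].
#' @param n_frames,min_views passed to [analyze_session()].
#' @param form,cv_variant,sem_variant passed to [reliability_report()].
#' @return List with `report` (data.frame) and `pairs` (list of
#'   `aligned_pair`s).
#' @examples
#' \donttest{
#' res <- run_validation(sim_config(seed = 42, repetitions = 2))
#' res$report[, c("ICC", "ci_lower", "ci_upper")]
#' }
#' @export
run_validation <- function(config = sim_config(), n_frames = 100L,
                           min_views = 2L, form = "ICC21",
                           cv_variant = "dahlberg", sem_variant = "rooted") {
  bundles <- simulate_paired_session(config)
  pairs <- lapply(bundles, function(b) {
    p <- analyze_session(b, n_frames = n_frames, min_views = min_views)$pair
    p$provenance$participant <- b$repetition
    p
  })
  report <- reliability_report(pairs, form = form, cv_variant = cv_variant,
                               sem_variant = sem_variant)
  list(report = report, pairs = pairs)
}
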