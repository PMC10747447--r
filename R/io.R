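#' Read and write a camera rig as JSON
#'
#' One record per camera: `name`, `focal_px`, `principal_px`,
#' `image_size_px`, `rotation` (3x3, row-major) and `translation`, such
#' that the projection is `intrinsics %*% cbind(rotation, translation)`.
#'
#' @param rig list of [camera_model()]s.
#' @param path output file.
#' @return `read_rig_json()` returns the list of cameras.
#' @export
write_rig_json <- function(rig, path) {
  recs <- lapply(rig, function(cm) {
    list(name = cm$name, focal_px = cm$focal_px,
         principal_px = cm$principal_px, image_size_px = cm$image_size_px,
         rotation = as.vector(t(cm$rotation)),
         translation = cm$translation)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rig_json
#' @export
read_rig_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    camera_model(name = r$name,
                 focal_px = unlist(r$focal_px),
                 principal_px = unlist(r$principal_px),
                 image_size_px = unlist(r$image_size_px),
                 rotation = matrix(unlist(r$rotation), 3L, 3L, byrow = TRUE),
                 translation = unlist(r$translation))
  })
}

#' Read and write a per-camera 2D keypoint series as CSV
#'
#' Columns: `frame`, `time_s`, then `<keypoint>_x`, `<keypoint>_y` in
#' pixels. Missing observations are written as empty cells. Comment lines
#' (`#`) record the camera name and rate.
#'
#' @param series a [keypoint_series()].
#' @param path file path.
#' @return `read_keypoints_csv()` returns a [keypoint_series()].
#' @export
write_keypoints_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# camera: %s", attr(series, "camera")),
               sprintf("# rate_hz: %g", attr(series, "rate_hz"))), con)
  utils::write.table(as.data.frame(series), con, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path) {
  hdr <- read_comment_header(path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path,
                              conditionMessage(e))
  )
  if (!all(c("frame", "time_s") %in% names(df))) {
    stopf("%s: keypoint CSV needs 'frame' and 'time_s' columns", path)
  }
  keypoint_series(df$frame, df$time_s,
                  df[, setdiff(names(df), c("frame", "time_s")),
                     drop = FALSE],
                  camera = hdr[["camera"]] %||% basename(path),
                  rate_hz = as.numeric(hdr[["rate_hz"]] %||% NA))
}

#' Read and write an angle trace as CSV
#'
#' Columns `frame`, `time_s`, `angle_deg`; `#` comment lines record the
#' task, rate, sign convention and (optionally) the generating seed.
#'
#' @param trace an [angle_trace()].
#' @param path file path.
#' @param seed optional seed to record in the header.
#' @return `read_angle_trace_csv()` returns an [angle_trace()].
#' @export
write_angle_trace_csv <- function(trace, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# task: %s", trace$task),
           sprintf("# rate_hz: %g", trace$rate_hz),
           sprintf("# convention: %s", trace$convention))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed: %d", as.integer(seed)))
  writeLines(hdr, con)
  df <- data.frame(frame = seq_along(trace$angle_deg) - 1L,
                   time_s = trace$time_s, angle_deg = trace$angle_deg)
  utils::write.table(df, con, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_trace_csv
#' @export
read_angle_trace_csv <- function(path) {
  hdr <- read_comment_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  angle_trace(df$angle_deg,
              rate_hz = as.numeric(hdr[["rate_hz"]]),
              task = hdr[["task"]],
              convention = hdr[["convention"]],
              time_s = df$time_s)
}

## "# key: value" comment lines at the top of a CSV -> named character list
read_comment_header <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) out[[trimws(m[2L])]] <- trimws(m[3L])
  }
  out
}

#' Write an aligned trace pair as CSV
#'
#' Columns `grid_index` (0 to n-1), `t_norm`, `test_deg`, `ref_deg`, with
#' provenance recorded in `#` comment lines.
#'
#' @param pair an `aligned_pair` (see [pair_traces()]).
#' @param path file path.
#' @export
write_pair_csv <- function(pair, path) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- pair$provenance
  hdr <- c(sprintf("# task: %s", pair$task),
           sprintf("# convention: %s", pair$convention),
           vapply(names(prov), function(k) {
             sprintf("# %s: %s", k, as.character(prov[[k]]))
           }, character(1L)))
  writeLines(hdr, con)
  df <- data.frame(grid_index = seq_along(pair$test) - 1L,
                   t_norm = pair$grid,
                   test_deg = pair$test,
                   ref_deg = pair$reference)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a triangulated 3D series as CSV
#'
#' Columns `frame`, `time_s`, `<keypoint>_x/_y/_z` (metres) and
#' `<keypoint>_residual_px`.
#'
#' @param skel a `skeleton_series`.
#' @param path file path.
#' @export
write_skeleton_csv <- function(skel, path) {
  kp <- dimnames(skel$xyz)[[2L]]
  cols <- list(frame = seq_len(dim(skel$xyz)[1L]) - 1L, time_s = skel$time_s)
  for (j in seq_along(kp)) {
    cols[[paste0(kp[j], "_x")]] <- skel$xyz[, j, 1L]
    cols[[paste0(kp[j], "_y")]] <- skel$xyz[, j, 2L]
    cols[[paste0(kp[j], "_z")]] <- skel$xyz[, j, 3L]
    if (!is.null(skel$residual_px)) {
      cols[[paste0(kp[j], "_residual_px")]] <- skel$residual_px[, j]
    }
  }
  utils::write.table(as.data.frame(cols), path, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated session to a directory
#'
#' Emits the rig JSON, one keypoint CSV per camera, the reference and
#' ground-truth angle CSVs, and a manifest recording the seed and a hash of
#' the configuration.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rig_json(bundle$rig, file.path(dir, "rig.json"))
  view_files <- vapply(bundle$views, function(v) {
    f <- file.path(dir, sprintf("keypoints_%s.csv", attr(v, "camera")))
    write_keypoints_csv(v, f)
    basename(f)
  }, character(1L))
  write_angle_trace_csv(bundle$reference, file.path(dir, "reference.csv"),
                        seed = bundle$noise$seed)
  write_angle_trace_csv(bundle$truth, file.path(dir, "ground_truth.csv"),
                        seed = bundle$noise$seed)
  manifest <- list(seed = bundle$noise$seed,
                   repetition = bundle$repetition,
                   task = bundle$config$task,
                   config_hash = config_hash(bundle$config),
                   views = as.vector(view_files),
                   reference = "reference.csv",
                   ground_truth = "ground_truth.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' MD5 hash of a simulation configuration
#' @param cfg a `sim_config`.
#' @return Character MD5 digest of the canonical JSON serialisation.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Load a written session directory for analysis
#'
#' Reads the artifacts of [write_session()] back into a bundle that
#' [analyze_session()] accepts.
#'
#' @param dir session directory containing `manifest.json`.
#' @return A list with `rig`, `views`, `reference`, `truth` and `config`
#'   fields.
#' @export
read_session <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  list(rig = read_rig_json(file.path(dir, "rig.json")),
       views = lapply(file.path(dir, mf$views), read_keypoints_csv),
       reference = read_angle_trace_csv(file.path(dir, mf$reference)),
       truth = if (file.exists(file.path(dir, mf$ground_truth))) {
         read_angle_trace_csv(file.path(dir, mf$ground_truth))
       },
       config = list(task = mf$task),
       repetition = mf$repetition)
}
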