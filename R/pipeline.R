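#' File-based validation pipeline
#'
#' Runs the full chain on on-disk inputs: read the rig and per-camera
#' keypoint CSVs, triangulate to 3D, extract the task angle, pair it with
#' the reference trace on the normalised grid, and compute the agreement
#' report. Intermediate artifacts (3D series, paired traces, report) are
#' written to `out_dir` when given.
#'
#' @param rig_path rig JSON file.
#' @param view_paths character vector of per-camera keypoint CSVs.
#' @param reference_path reference angle-trace CSV.
#' @param task task kind; defaults to the reference trace's task.
#' @param n_frames frames in the normalised grid (default 100).
#' @param min_views minimum cameras per reconstructed keypoint.
#' @param form ICC form for the report.
#' @param cv_variant,sem_variant statistic variants (see
#'   [cv_method_error()], [sem_measurement()]).
#' @param out_dir optional output directory for intermediate artifacts.
#' @param plots if `TRUE` (and `out_dir` given), writes an overlay plot of
#'   the paired traces as a PDF.
#' @return List with `report`, `pair`, `trace` and `skeleton`.
#' @export
run_pipeline <- function(rig_path, view_paths, reference_path, task = NULL,
                         n_frames = 100L, min_views = 2L, form = "ICC21",
                         cv_variant = "dahlberg", sem_variant = "rooted",
                         out_dir = NULL, plots = FALSE) {
  rig <- with_stage("read rig", rig_path, read_rig_json(rig_path))
  views <- lapply(view_paths, function(p) {
    with_stage("read keypoints", p, read_keypoints_csv(p))
  })
  reference <- with_stage("read reference", reference_path,
                          read_angle_trace_csv(reference_path))
  task <- task %||% reference$task
  skel <- with_stage("triangulate", rig_path,
                     triangulate_series(rig, views, min_views = min_views))
  message(sprintf("triangulated %d frames x %d keypoints (%d missing)",
                  dim(skel$xyz)[1L], dim(skel$xyz)[2L],
                  sum(is.na(skel$xyz[, , 1L]))))
  trace <- with_stage("angles", rig_path,
                      angle_trace_from_skeleton(skel, task))
  pair <- with_stage("align", reference_path,
                     pair_traces(trace, reference,
                                 n = n_frames,
                                 provenance = list(task = task)))
  message(sprintf("aligned windows: test frames %d..%d, reference %d..%d",
                  pair$windows$test$start, pair$windows$test$end,
                  pair$windows$reference$start, pair$windows$reference$end))
  report <- reliability_report(pair, form = form, cv_variant = cv_variant,
                               sem_variant = sem_variant)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_skeleton_csv(skel, file.path(out_dir, "skeleton_3d.csv"))
    write_pair_csv(pair, file.path(out_dir, "aligned_pair.csv"))
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    if (isTRUE(plots)) {
      grDevices::pdf(file.path(out_dir, "overlay.pdf"), width = 7,
                     height = 5)
      plot_aligned_pair(pair)
      grDevices::dev.off()
    }
  }
  list(report = report, pair = pair, trace = trace, skeleton = skel)
}

with_stage <- function(stage, path, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed on %s: %s", stage, path, conditionMessage(e))
  })
}
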