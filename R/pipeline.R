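# End-to-end pipeline entry points: simulate a benchmark, run
# segmentation + tracking on a stack, and evaluate against ground truth.
# Each writes its artifacts to disk and a run log with the complete
# effective configuration.

write_run_log <- function(dir, cfg, extra = list()) {
  log <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version =
                  as.character(utils::packageVersion("rodtrack"))),
           config_flatten(cfg), extra)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full segmentation + tracking pipeline
#'
#' Writes: label masks (16-bit PGM series under `labels/`), the track
#' table (`tracks.csv`), the lineage (`lineage.json`), growth statistics
#' (`growth.csv`) and a run log with the complete configuration.
#' Deterministic given the configuration.
#'
#' @param stack a [frame_stack()] (or path loadable by [load_stack()]).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the [track_stack()] result, invisibly.
#' @export
run_pipeline <- function(stack, out_dir, config = pipeline_config()) {
  if (is.character(stack))
    stack <- load_stack(stack, config$calibration,
                        config$frame_interval)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- track_stack(stack, config$seg, config$track, config$drlse,
                     calibration = config$calibration)
  dims <- dim(stack$frames[[1]])
  labels <- lapply(res$regions, regions_to_labels, dims = dims)
  save_stack(labels, file.path(out_dir, "labels"), prefix = "label",
             maxval = 65535L, calibration = config$calibration,
             frame_interval = config$frame_interval)
  utils::write.csv(track_table(res), file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  write_lineage_json(res$lineage, file.path(out_dir, "lineage.json"))
  utils::write.csv(growth_curves(res, config$frame_interval),
                   file.path(out_dir, "growth.csv"), row.names = FALSE)
  write_run_log(out_dir, config,
                list(n_frames = length(stack$frames),
                     n_trajectories = length(res$state$trajectories)))
  invisible(res)
}

#' Simulate a benchmark dataset to disk
#'
#' Writes rendered images (`images/`), ground-truth 16-bit label masks
#' (`gt_labels/`), the per-frame cell table (`gt_cells.csv`) and the
#' ground-truth lineage (`gt_lineage.json`).
#'
#' @param out_dir output directory.
#' @param n_frames,seed,n_init,... passed to [simulate_colony()].
#' @param noise_sd,blur_sd passed to [render_scene()].
#' @return the scene, invisibly.
#' @export
run_simulate <- function(out_dir, n_frames = 20L, seed = 1L,
                         n_init = 3L, noise_sd = 3.6, blur_sd = 1, ...) {
  scene <- simulate_colony(n_frames, seed = seed, n_init = n_init, ...)
  rend <- render_scene(scene, noise_sd = noise_sd, blur_sd = blur_sd)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_stack(rend$images, file.path(out_dir, "images"),
             prefix = "frame", maxval = 255L,
             calibration = scene$calibration,
             frame_interval = scene$frame_interval)
  save_stack(rend$labels, file.path(out_dir, "gt_labels"),
             prefix = "label", maxval = 65535L,
             calibration = scene$calibration,
             frame_interval = scene$frame_interval)
  utils::write.csv(gt_track_table(scene),
                   file.path(out_dir, "gt_cells.csv"), row.names = FALSE)
  write_lineage_json(scene$lineage,
                     file.path(out_dir, "gt_lineage.json"))
  invisible(scene)
}

# gt labels under the division leniency rule, per frame: cells in late
# septum phase (mothers about to divide) and daughters in their first
# frame
division_leniency <- function(scene) {
  n <- length(scene$frames)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    cells <- scene$frames[[t]]
    ids <- cells$id[cells$septum > 0.5]
    first <- cells$id[!is.na(cells$parent) &
                        scene$lineage$b[match(cells$id,
                                              scene$lineage$id)] == t]
    out[[t]] <- unique(c(ids, first))
  }
  out
}

#' Run the pipeline on a synthetic scene and evaluate it
#'
#' Renders the scene, tracks it, and evaluates segmentation (Dice,
#' TP/over/under/FN categories with the division leniency rule) and
#' tracking (MOTP, MOTA and its error ratios) against the exact ground
#' truth.
#'
#' @param scene a [simulate_colony()] scene.
#' @param config a [pipeline_config()] (calibration is taken from the
#'   scene).
#' @param noise_sd,blur_sd rendering parameters.
#' @param dist_max,iou_min evaluation thresholds.
#' @return list with `result` (the [track_stack()] output), `rendered`,
#'   and `eval` (the [evaluate_tracking()] report).
#' @export
evaluate_on_scene <- function(scene, config = NULL, noise_sd = 3.6,
                              blur_sd = 1, dist_max = 5, iou_min = 0.5) {
  if (is.null(config))
    config <- pipeline_config(calibration = scene$calibration,
                              frame_interval = scene$frame_interval)
  rend <- render_scene(scene, noise_sd = noise_sd, blur_sd = blur_sd)
  stack <- frame_stack(rend$images, scene$calibration,
                       scene$frame_interval)
  res <- track_stack(stack, config$seg, config$track, config$drlse,
                     calibration = scene$calibration)
  dims <- dim(rend$images[[1]])
  pred_labels <- lapply(res$regions, regions_to_labels, dims = dims)
  tt <- track_table(res)
  pred_tab <- data.frame(frame = tt$frame, id = tt$trajectory_id,
                         x = tt$centroid_x + 1, y = tt$centroid_y + 1)
  gt <- gt_track_table(scene)
  gt_tab <- data.frame(frame = gt$frame, id = gt$id, parent = gt$parent,
                       x = gt$x_px, y = gt$y_px)
  ev <- evaluate_tracking(pred_tab, gt_tab, pred_labels, rend$labels,
                          division_labels_by_frame =
                            division_leniency(scene),
                          dist_max = dist_max, iou_min = iou_min)
  list(result = res, rendered = rend, eval = ev)
}

#' Evaluate saved predictions against saved ground truth
#'
#' @param pred_dir a [run_pipeline()] output directory.
#' @param gt_dir a [run_simulate()] output directory.
#' @param out_path optional JSON report path.
#' @param dist_max,iou_min evaluation thresholds.
#' @return the evaluation report list.
#' @export
run_evaluate <- function(pred_dir, gt_dir, out_path = NULL,
                         dist_max = 5, iou_min = 0.5) {
  if (!dir.exists(gt_dir)) stop("missing ground truth: ", gt_dir)
  if (!dir.exists(pred_dir)) stop("missing predictions: ", pred_dir)
  tt <- utils::read.csv(file.path(pred_dir, "tracks.csv"))
  pred_tab <- data.frame(frame = tt$frame, id = tt$trajectory_id,
                         x = tt$centroid_x + 1, y = tt$centroid_y + 1)
  gt <- utils::read.csv(file.path(gt_dir, "gt_cells.csv"))
  gt_tab <- data.frame(frame = gt$frame, id = gt$id, parent = gt$parent,
                       x = gt$x_px, y = gt$y_px)
  pred_stack <- load_stack(file.path(pred_dir, "labels"))
  gt_stack <- load_stack(file.path(gt_dir, "gt_labels"))
  ev <- evaluate_tracking(pred_tab, gt_tab, pred_stack$frames,
                          gt_stack$frames, dist_max = dist_max,
                          iou_min = iou_min)
  report <- list(motp = ev$motp, mota = ev$mota, seg = ev$seg,
                 mean_dice = ev$mean_dice, thresholds = ev$thresholds)
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  ev
}
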