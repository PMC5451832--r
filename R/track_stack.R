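# End-to-end segmentation-feeds-tracking over a whole stack: first-frame
# DRLSE segmentation, then per frame region propagation, width and septum
# splits, capture of entering cells and identity assignment.

#' Track a whole image stack
#'
#' Frame 1 is segmented from scratch ([segment_first_frame()]). For every
#' subsequent frame each live trajectory's region is propagated by
#' windowed DRLSE coevolution ([propagate_region()]); over-wide regions
#' are split transversely ([split_by_width()]); the septum criterion
#' ([detect_division()], on regions longer than
#' `track_cfg$min_div_len_factor * r_s`) and physical separation of a
#' region into two components both trigger division events; cells newly
#' entering the field are captured ([capture_new_cells()]); and
#' identities are finalized by [assign_optimal()].
#'
#' @param stack a [frame_stack()] or a plain list of image matrices.
#' @param seg_cfg a [seg_config()].
#' @param track_cfg a [track_config()].
#' @param drlse a [drlse_params()].
#' @param calibration micrometres per pixel (taken from the stack when it
#'   carries one).
#' @param verbose print per-frame progress.
#' @return list with `regions` (per-frame lists of cell regions labelled
#'   by trajectory id), `state` (the final [tracking_state()]), `lineage`
#'   (data.frame id, parent, b, d) and `events` (data.frame of division /
#'   lost-cell events).
#' @export
track_stack <- function(stack, seg_cfg = seg_config(),
                        track_cfg = track_config(),
                        drlse = drlse_params(), calibration = NULL,
                        verbose = FALSE) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (is.null(calibration))
    calibration <- if (inherits(stack, "frame_stack")) stack$calibration
                   else seg_cfg$calibration
  seg_cfg$calibration <- calibration
  n <- length(frames)
  stopifnot(n >= 1L)
  dims <- dim(frames[[1]])
  min_div_len <- track_cfg$min_div_len_factor * seg_cfg$r_s

  regions_by_frame <- vector("list", n)
  events <- list()
  log_event <- function(frame, type, id)
    events[[length(events) + 1L]] <<-
      data.frame(frame = frame, type = type, id = id)

  first <- segment_first_frame(frames[[1]], seg_cfg, drlse)
  trajs <- list()
  for (reg in first) {
    tr <- new_trajectory(reg$label, 1L, matrix(reg$centroid, 1))
    tr$regions[["1"]] <- reg
    trajs[[as.character(reg$label)]] <- tr
  }
  state <- tracking_state(unname(trajs), 1L, calibration)
  regions_by_frame[[1]] <- first

  for (t in seq_len(n)[-1]) {
    img <- frames[[t]]
    sm <- smooth_image(img, drlse$sigma)
    g <- edge_indicator(img, drlse$sigma)
    inv <- invert_image(sm)
    claimed <- matrix(FALSE, dims[1], dims[2])
    cands <- list()

    live <- Filter(function(tr) tr$d == t - 1L, state$trajectories)
    # coevolution: every live cell's previous core is frozen up front so
    # that a cell processed earlier cannot creep into a touching
    # neighbour that has not claimed its pixels yet
    cores <- lapply(live, function(tr)
      erode_mask(tr$regions[[as.character(t - 1L)]]$mask, 1L))
    pending_core <- Reduce(`|`, cores, matrix(FALSE, dims[1], dims[2]))
    for (k in seq_along(live)) {
      tr <- live[[k]]
      prev <- tr$regions[[as.character(t - 1L)]]
      pending_core <- pending_core & !cores[[k]]
      cand <- propagate_region(prev, img, track_cfg, drlse,
                               claimed = claimed | pending_core,
                               smoothed = sm, g = g,
                               thr_window = seg_cfg$thr_window,
                               thr_offset = seg_cfg$thr_offset)
      if (is.null(cand)) { log_event(t, "lost", tr$id); next }
      claimed <- claimed | cand$mask
      cands[[length(cands) + 1L]] <- list(region = cand, src = tr$id)
    }

    # septum threshold from all tracked contours' boundary bands
    bnd_vals <- unlist(lapply(cands, function(it)
      inv[boundary_band(it$region$mask)]))
    r_m <- if (length(bnd_vals) > 0L)
      septum_threshold(bnd_vals, track_cfg$tau) else Inf

    items <- list()
    for (it in cands) {
      reg <- it$region
      # physical separation into two complete cells
      if (reg$length_um >= min_div_len) {
        comps <- split_components(reg, min_len_um = seg_cfg$r_s)
        if (!is.null(comps)) {
          items[[length(items) + 1L]] <-
            list(regions = comps, src = it$src, division = TRUE)
          log_event(t, "division", it$src)
          next
        }
      }
      # not a division: a fragmented region keeps its largest component
      lab <- label_components(reg$mask, 4L)
      if (max(lab) > 1L) {
        sz <- tabulate(lab[lab > 0L])
        reg <- make_region(lab == which.max(sz), reg$label, t,
                           calibration)
      }
      # septum criterion along the major axis
      if (reg$length_um >= min_div_len) {
        prof <- axis_profile(reg, inv, axis = "major")
        pos <- detect_division(prof, r_m)
        if (!is.null(pos)) {
          halves <- split_region(reg, pos, prof, axis = "major")
          if (!is.null(halves)) {
            items[[length(items) + 1L]] <-
              list(regions = halves, src = it$src, division = TRUE)
            log_event(t, "division", it$src)
            next
          }
        }
      }
      # width criterion
      ws <- split_by_width(reg, track_cfg$r_w, inv, r_m)
      if (length(ws) == 2L) {
        items[[length(items) + 1L]] <-
          list(regions = ws, src = it$src, division = TRUE)
        log_event(t, "division", it$src)
      } else {
        items[[length(items) + 1L]] <- list(region = reg, src = it$src)
      }
    }

    occupied <- matrix(FALSE, dims[1], dims[2])
    for (it in items)
      for (rg in if (isTRUE(it$division)) it$regions else list(it$region))
        occupied <- occupied | rg$mask
    fresh <- capture_new_cells(img, occupied, seg_cfg, drlse,
                               frame = t)
    for (rg in fresh) {
      items[[length(items) + 1L]] <- list(region = rg, src = NA_integer_)
      log_event(t, "new", NA_integer_)
    }

    state <- assign_optimal(state, items, t, track_cfg)
    regions_by_frame[[t]] <- attr(state, "frame_regions")
    if (verbose)
      message(sprintf("frame %d: %d regions, %d trajectories", t,
                      length(regions_by_frame[[t]]),
                      length(state$trajectories)))
  }
  state$n_frames <- n

  lineage <- state_lineage(state)
  list(regions = regions_by_frame, state = state, lineage = lineage,
       events = if (length(events) > 0L) do.call(rbind, events)
                else data.frame(frame = integer(0), type = character(0),
                                id = integer(0)))
}

# lineage table of a tracking state
state_lineage <- function(state) {
  trs <- state$trajectories
  if (length(trs) == 0L)
    return(data.frame(id = integer(0), parent = integer(0),
                      b = integer(0), d = integer(0)))
  data.frame(
    id = vapply(trs, `[[`, integer(1), "id"),
    parent = vapply(trs, function(tr)
      if (is.null(tr$parent) || is.na(tr$parent)) NA_integer_
      else as.integer(tr$parent), integer(1)),
    b = vapply(trs, `[[`, integer(1), "b"),
    d = vapply(trs, `[[`, integer(1), "d"),
    row.names = NULL)
}

#' Track table of a tracking result
#'
#' One row per cell per frame. Coordinates are 0-based pixels
#' (origin top-left), lengths and widths in micrometres.
#'
#' @param result a [track_stack()] result.
#' @return data.frame with frame, trajectory_id, parent_id, centroid_x,
#'   centroid_y, area_px, length_um, width_um, divided_flag.
#' @export
track_table <- function(result) {
  rows <- list()
  for (t in seq_along(result$regions))
    for (reg in result$regions[[t]]) {
      tr <- result$state$trajectories[[as.character(reg$label)]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, trajectory_id = reg$label,
        parent_id = if (!is.null(tr) && !is.na(tr$parent)) tr$parent
                    else NA_integer_,
        centroid_x = reg$centroid[["x"]] - 1,
        centroid_y = reg$centroid[["y"]] - 1,
        area_px = reg$area, length_um = reg$length_um,
        width_um = reg$width_um,
        divided_flag = !is.null(tr) && !is.null(tr$children) &&
          tr$d == t)
    }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), trajectory_id = integer(0),
                      parent_id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area_px = integer(0),
                      length_um = numeric(0), width_um = numeric(0),
                      divided_flag = logical(0)))
  do.call(rbind, rows)
}
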