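# First-frame segmentation and capture of newly entering cells. Rough
# interiors are found by adaptive thresholding (dark cells on a bright
# background), each seed is grown independently by DRLSE, and the final
# components are filtered by the minimum-size threshold r_s and (for
# fresh detections) by border contact.

#' Adaptive-threshold seeds
#'
#' A pixel is a seed candidate when it is darker than the local mean over
#' a `thr_window` box minus `thr_offset`. Components smaller than
#' `min_seed_area` pixels are dropped.
#'
#' @param image preprocessed (smoothed) image.
#' @param cfg a [seg_config()] object.
#' @return logical seed mask (possibly empty).
#' @export
initial_seeds <- function(image, cfg = seg_config()) {
  local_mean <- cpp_conv_sep(image, box_kernel(cfg$thr_window))
  mask <- image < local_mean - cfg$thr_offset
  if (!any(mask)) return(mask)
  lab <- label_components(mask, 4L)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz >= cfg$min_seed_area)
  mask[] <- lab %in% keep & lab > 0L
  mask
}

# grow one seed component by DRLSE on a cropped window; returns a logical
# full-size mask or NULL. `claimed` pixels are frozen (other labels).
grow_seed <- function(seed_mask, g, drlse, claimed = NULL,
                      margin = 12L) {
  idx <- which(seed_mask, arr.ind = TRUE)
  bbox <- c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
            cmin = min(idx[, 2]), cmax = max(idx[, 2]))
  win <- crop_window(bbox, dim(g), margin)
  phi <- phi_init(seed_mask[win$rows, win$cols, drop = FALSE], drlse$c0)
  fr <- if (is.null(claimed)) NULL else
    claimed[win$rows, win$cols, drop = FALSE]
  res <- evolve(phi, g[win$rows, win$cols, drop = FALSE], drlse,
                freeze_mask = fr)
  sub <- res$phi < 0
  if (!is.null(fr)) sub <- sub & !fr
  if (!any(sub)) return(NULL)
  # keep components connected to the seed
  lab <- label_components(sub, 4L)
  hit <- unique(lab[seed_mask[win$rows, win$cols, drop = FALSE] & lab > 0L])
  hit <- hit[hit > 0L]
  if (length(hit) == 0L) {
    sz <- tabulate(lab[lab > 0L])
    hit <- which.max(sz)
  }
  full <- matrix(FALSE, nrow(g), ncol(g))
  full[win$rows, win$cols] <- lab %in% hit
  full
}

# shared scheme: seeds -> independent DRLSE growth -> r_s / border filters
segment_scheme <- function(image, cfg, drlse, forbidden = NULL,
                           first_label = 1L, frame = 1L) {
  sm <- smooth_image(image, drlse$sigma)
  g <- edge_indicator(image, drlse$sigma)
  seeds <- initial_seeds(sm, cfg)
  if (!is.null(forbidden)) seeds <- seeds & !dilate_mask(forbidden, 2L)
  if (!any(seeds)) return(list())
  lab <- label_components(seeds, 4L)
  sz <- tabulate(lab[lab > 0L])
  comp_ids <- which(sz >= cfg$min_seed_area)
  claimed <- if (is.null(forbidden)) matrix(FALSE, nrow(image), ncol(image))
             else forbidden
  regions <- list()
  nxt <- as.integer(first_label)
  r_s_px2 <- (cfg$r_s / cfg$calibration)^2
  for (cid in comp_ids) {
    seed <- lab == cid
    mask <- grow_seed(seed, g, drlse, claimed)
    if (is.null(mask)) next
    reg <- make_region(mask, nxt, frame, cfg$calibration)
    if (reg$length_um < cfg$r_s) next
    if (cfg$remove_border && reg$touches_border) next
    claimed <- claimed | mask
    regions[[length(regions) + 1L]] <- reg
    nxt <- nxt + 1L
  }
  regions
}

#' Segment the first frame
#'
#' Each adaptive-threshold seed is evolved independently by DRLSE (with
#' already-claimed pixels frozen so masks stay disjoint). Final components
#' with pole-to-pole length below `r_s` are eliminated as debris, and
#' objects touching the image border are removed. Survivors are labelled
#' 1..n.
#'
#' @param image first frame (raw, un-smoothed).
#' @param cfg a [seg_config()] object.
#' @param drlse a [drlse_params()] object.
#' @return list of [make_region()] cell regions.
#' @export
segment_first_frame <- function(image, cfg = seg_config(),
                                drlse = drlse_params()) {
  segment_scheme(image, cfg, drlse)
}

#' Capture cells newly entering the field of view
#'
#' Runs the first-frame segmentation scheme restricted to the complement
#' of the already-tracked area. Returned regions are disjoint from
#' `occupied`; the caller assigns fresh trajectory ids.
#'
#' @param image current frame (raw).
#' @param occupied logical matrix: union of all masks already tracked in
#'   this frame.
#' @param cfg a [seg_config()] object.
#' @param drlse a [drlse_params()] object.
#' @param first_label label of the first captured region.
#' @param frame frame index stored in the regions.
#' @return list of cell regions (possibly empty).
#' @export
capture_new_cells <- function(image, occupied, cfg = seg_config(),
                              drlse = drlse_params(), first_label = 1L,
                              frame = 1L) {
  stopifnot(identical(dim(image), dim(occupied)))
  if (all(occupied)) return(list())
  segment_scheme(image, cfg, drlse, forbidden = occupied,
                 first_label = first_label, frame = frame)
}
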