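# Frame-to-frame propagation of cell regions by windowed DRLSE
# coevolution, and division detection from the intensity profile along a
# cell's axis.
#
# Intensity convention: cells are dark on a bright background. Division
# detection operates on the *inverted* smoothed image (max - I), in which
# a cell interior is a high plateau and the septum (which brightens
# toward background as constriction completes) is a local *minimum*; the
# criterion is then literally "local minimum l_m below the threshold
# r_m = mean + tau * sd of the tracked contours' boundary-band
# intensities".

invert_image <- function(image) max(image) - image

#' Split a region into small windows
#'
#' Axis-aligned grid of side `round(w / calibration)` pixels over the
#' region's bounding box; only windows intersecting the mask are
#' returned, and their union covers the mask.
#'
#' @param region a [make_region()] cell region.
#' @param w window side in micrometres.
#' @param calibration micrometres per pixel.
#' @return list of windows, each `c(rmin, rmax, cmin, cmax)`.
#' @export
split_into_windows <- function(region, w = 0.6, calibration = 0.15) {
  side <- as.integer(round(w / calibration))
  if (side < 1) stop("window size below 1 px: w = ", w, " um at ",
                     calibration, " um/px")
  bb <- region$bbox
  rstarts <- seq.int(bb[["rmin"]], bb[["rmax"]], by = side)
  cstarts <- seq.int(bb[["cmin"]], bb[["cmax"]], by = side)
  wins <- list()
  for (r0 in rstarts) for (c0 in cstarts) {
    r1 <- min(r0 + side - 1L, bb[["rmax"]])
    c1 <- min(c0 + side - 1L, bb[["cmax"]])
    if (any(region$mask[r0:r1, c0:c1]))
      wins[[length(wins) + 1L]] <- c(rmin = r0, rmax = r1,
                                     cmin = c0, cmax = c1)
  }
  wins
}

#' Classify windows as boundary or interior
#'
#' A window is "boundary" when the maximum gradient magnitude of the
#' smoothed image inside it exceeds an Otsu split of the per-window
#' maxima (cell boundaries carry high intensity gradients). If the split
#' is degenerate (all windows alike) every window is classified interior.
#'
#' @param windows from [split_into_windows()].
#' @param image smoothed image.
#' @param grad_mag optional precomputed gradient magnitude.
#' @return list with integer vectors `boundary` and `interior` (indices
#'   into `windows`) and the per-window `values`.
#' @export
classify_windows <- function(windows, image, grad_mag = NULL) {
  if (is.null(grad_mag)) grad_mag <- image_gradient(image)$mag
  vals <- vapply(windows, function(wd)
    max(grad_mag[wd[["rmin"]]:wd[["rmax"]], wd[["cmin"]]:wd[["cmax"]]]),
    numeric(1))
  if (length(vals) == 0L)
    return(list(boundary = integer(0), interior = integer(0),
                values = vals))
  if (diff(range(vals)) < 1e-9)
    return(list(boundary = integer(0),
                interior = seq_along(windows), values = vals))
  thr <- otsu_threshold(vals)
  boundary <- which(vals > thr)
  list(boundary = boundary,
       interior = setdiff(seq_along(windows), boundary), values = vals)
}

#' Propagate a cell region to the next frame
#'
#' The previous region is split into windows; boundary windows are
#' eliminated; the remaining interior pixels overlapping the previous
#' mask form the intersection V, which is grown by DRLSE to the cell's
#' boundary in the current frame. Pixels already claimed by other labels
#' are frozen so contours can never merge. Evolved components are kept if
#' they overlap the previous mask; detached components must pass a
#' rod-shape and size criterion (eccentricity >= 0.8 and area >= half the
#' previous area) and are otherwise discarded.
#'
#' @param prev the cell's region in frame t-1.
#' @param image current raw frame.
#' @param cfg a [track_config()] object.
#' @param drlse a [drlse_params()] object.
#' @param claimed logical matrix of pixels already claimed by other
#'   labels in the current frame (or NULL).
#' @param smoothed,g optional precomputed smoothed image and edge
#'   indicator for the current frame.
#' @param thr_window,thr_offset adaptive-threshold settings used to
#'   recover the overlap region when the windowed route leaves too
#'   little interior (cells barely wider than the window).
#' @return a cell region (possibly with a multi-component mask when the
#'   cell has physically separated), or NULL if the cell is lost.
#' @export
propagate_region <- function(prev, image, cfg = track_config(),
                             drlse = drlse_params(), claimed = NULL,
                             smoothed = NULL, g = NULL,
                             thr_window = 25L, thr_offset = 30) {
  if (is.null(smoothed)) smoothed <- smooth_image(image, drlse$sigma)
  if (is.null(g)) g <- edge_indicator(image, drlse$sigma)
  cal <- prev$calibration
  wins <- split_into_windows(prev, cfg$w, cal)
  cls <- classify_windows(wins, smoothed)

  seed <- matrix(FALSE, nrow(image), ncol(image))
  for (k in cls$interior) {
    wd <- wins[[k]]
    seed[wd[["rmin"]]:wd[["rmax"]], wd[["cmin"]]:wd[["cmax"]]] <- TRUE
  }
  seed <- seed & prev$mask
  if (!is.null(claimed)) seed <- seed & !claimed
  if (!any(seed)) {
    # degenerate fallback (e.g. cell thinner than the window): use the
    # whole previous mask as the overlap region
    seed <- prev$mask
    if (!is.null(claimed)) seed <- seed & !claimed
    if (!any(seed)) return(NULL)
  }
  # V: interior components overlapping the previous mask
  lab <- label_components(seed, 4L)
  keep <- sort(unique(lab[prev$mask & lab > 0L]))
  if (length(keep) == 0L) return(NULL)
  V <- matrix(lab %in% keep, nrow(image), ncol(image))
  # Augment V with the current frame's interior evidence (adaptive
  # threshold restricted to the previous region's neighbourhood): at this
  # calibration cells are barely wider than the window, so boundary
  # windows alone leave almost no interior. The result is still the
  # intersection of the previous region and the current cell interior.
  local_mean <- cpp_conv_sep(smoothed, box_kernel(thr_window))
  dark <- smoothed < local_mean - thr_offset
  Vf <- dark & dilate_mask(prev$mask, 4L)
  if (!is.null(claimed)) Vf <- Vf & !claimed
  if (any(Vf)) {
    labf <- label_components(Vf, 4L)
    keepf <- sort(unique(labf[prev$mask & labf > 0L]))
    Vf <- matrix(labf %in% keepf & labf > 0L, nrow(image), ncol(image))
    V <- V | Vf
  }
  # V stays confined to the previous region's neighbourhood: a dark
  # bridge to a touching neighbour must not swallow it component-wise
  V <- V & dilate_mask(prev$mask, 3L)
  if (!any(V)) return(NULL)

  side <- max(2L, round(cfg$w / cal))
  win <- crop_window(prev$bbox, dim(image), margin = 10L + side)
  gw <- g[win$rows, win$cols, drop = FALSE]
  frbase <- if (is.null(claimed)) matrix(FALSE, length(win$rows),
                                         length(win$cols)) else
    claimed[win$rows, win$cols, drop = FALSE]

  # coevolve the components of V with mutual freezing: a physically
  # separated pair (post-division daughters share the label until the
  # split is recognized) must not re-merge across the gap
  Vw <- V[win$rows, win$cols, drop = FALSE]
  labV <- label_components(Vw, 4L)
  szV <- tabulate(labV[labV > 0L])
  big <- order(szV, decreasing = TRUE)
  big <- big[szV[big] >= max(4L, 0.15 * sum(szV))]
  big <- utils::head(big, 3L)
  small_ids <- setdiff(seq_along(szV), big)
  sub <- matrix(FALSE, length(win$rows), length(win$cols))
  if (length(big) > 1L) {
    for (cid in big) {
      phi <- phi_init(labV == cid, drlse$c0)
      # 1-px moat around already-evolved siblings: same-label components
      # must stay disconnected, not merely non-overlapping
      moat <- frbase | dilate_mask(sub, 1L)
      res <- evolve(phi, gw, drlse, freeze_mask = moat)
      sub <- sub | (res$phi < 0 & !moat)
    }
    if (length(small_ids) > 0L)
      sub <- sub | (labV %in% small_ids)
  } else {
    phi <- phi_init(Vw, drlse$c0)
    res <- evolve(phi, gw, drlse, freeze_mask = frbase)
    sub <- res$phi < 0 & !frbase
  }
  if (!any(sub)) return(NULL)

  # component filtering: keep components overlapping the previous mask;
  # detached ones must look like a rod of comparable size
  labs <- label_components(sub, 4L)
  prev_sub <- prev$mask[win$rows, win$cols, drop = FALSE]
  comp_ids <- seq_len(max(labs))
  keep2 <- integer(0)
  for (cid in comp_ids) {
    cm <- labs == cid
    if (any(cm & prev_sub)) { keep2 <- c(keep2, cid); next }
    full_tmp <- matrix(FALSE, nrow(image), ncol(image))
    full_tmp[win$rows, win$cols] <- cm
    rg <- make_region(full_tmp, 0L, prev$frame, cal)
    if (rg$eccentricity >= 0.8 && rg$area >= prev$area / 2)
      keep2 <- c(keep2, cid)
  }
  if (length(keep2) == 0L) return(NULL)
  full <- matrix(FALSE, nrow(image), ncol(image))
  full[win$rows, win$cols] <- labs %in% keep2
  make_region(full, prev$label, prev$frame + 1L, cal)
}

#' Intensity profile along a cell's axis
#'
#' Samples the supplied image at 1-px arc steps along the region's
#' best-fit major (or minor) axis, following the mask's transverse
#' centre of mass at each axial position (the spine) so that bent cells
#' and freshly separated pairs are sampled through their mid-line, and
#' averaging over a 3-px transverse band. Records the deepest qualifying
#' local minimum (an interior extremum at least 2 px from either pole).
#'
#' @param region a cell region.
#' @param image image to sample, typically the *inverted* smoothed frame
#'   so that a septum shows as a local minimum.
#' @param axis `"major"` (default) or `"minor"`.
#' @return list with `positions` (arc-length offsets from the centroid,
#'   px), `intensities`, and `l_m` / `l_m_index` (NULL / NA when no
#'   qualifying extremum exists).
#' @export
axis_profile <- function(region, image, axis = c("major", "minor")) {
  axis <- match.arg(axis)
  cal <- region$calibration
  if (axis == "major") {
    u <- region$major_axis
    len_px <- region$length_um / cal
  } else {
    u <- c(-region$major_axis[2], region$major_axis[1])
    len_px <- region$width_um / cal
  }
  n <- max(3L, round(len_px))
  offs <- seq(-(n - 1) / 2, (n - 1) / 2, length.out = n)
  v <- c(-u[2], u[1])   # transverse unit vector
  cx <- region$centroid[["x"]]; cy <- region$centroid[["y"]]
  # spine: transverse centre of mass of the mask per axial slab
  idx <- which(region$mask, arr.ind = TRUE)
  s_co <- (idx[, 2] - cx) * u[1] + (idx[, 1] - cy) * u[2]
  t_co <- (idx[, 2] - cx) * v[1] + (idx[, 1] - cy) * v[2]
  tc <- vapply(offs, function(s0) {
    w <- abs(s_co - s0) <= 1
    if (any(w)) mean(t_co[w]) else NA_real_
  }, numeric(1))
  if (anyNA(tc)) {
    good <- which(!is.na(tc))
    tc <- if (length(good) >= 2L)
      stats::approx(good, tc[good], seq_len(n), rule = 2)$y
    else rep(0, n)
  }
  if (n >= 3L) {
    tsm <- as.numeric(stats::filter(tc, rep(1 / 3, 3), sides = 2))
    tc <- ifelse(is.na(tsm), tc, tsm)
  }
  inten <- numeric(n)
  for (b in -1:1) {
    xs <- cx + offs * u[1] + (tc + b) * v[1]
    ys <- cy + offs * u[2] + (tc + b) * v[2]
    inten <- inten + bilinear(image, xs, ys)
  }
  inten <- inten / 3
  prof <- list(positions = offs, intensities = inten,
               l_m = NULL, l_m_index = NA_integer_)
  if (n >= 5L) {
    # qualifying minima need prominence above the rasterization ripple:
    # both flanks (within 3 samples) must rise by >= 4% of the profile
    # dynamic range
    prom <- 0.04 * diff(range(inten))
    cand <- integer(0)
    for (i in 3:(n - 2))
      if (inten[i] < inten[i - 1] && inten[i] <= inten[i + 1]) {
        lf <- max(inten[max(1, i - 3):(i - 1)])
        rt <- max(inten[(i + 1):min(n, i + 3)])
        if (min(lf, rt) - inten[i] >= prom) cand <- c(cand, i)
      }
    if (length(cand) > 0L) {
      best <- cand[which.min(inten[cand])]
      prof$l_m <- inten[best]
      prof$l_m_index <- best
    }
  }
  prof
}

#' Septum threshold
#'
#' `r_m = mean + tau * sd` of the intensities of all tracked cells'
#' boundary-band pixels in the current frame.
#'
#' @param boundary_pixels numeric vector of boundary-band intensities.
#' @param tau threshold multiplier.
#' @return scalar r_m.
#' @export
septum_threshold <- function(boundary_pixels, tau = 1.2) {
  if (length(boundary_pixels) == 0L)
    stop("septum_threshold: empty boundary sample")
  s <- if (length(boundary_pixels) > 1L) stats::sd(boundary_pixels) else 0
  mean(boundary_pixels) + tau * s
}

#' Detect a division from an axis profile
#'
#' Returns the index of the deepest qualifying local minimum if its value
#' `l_m` lies strictly below the threshold `r_m`, otherwise NULL.
#'
#' @param profile from [axis_profile()].
#' @param r_m threshold from [septum_threshold()].
#' @return integer sample index of the split position, or NULL.
#' @export
detect_division <- function(profile, r_m) {
  if (is.null(profile$l_m)) return(NULL)
  if (profile$l_m < r_m) profile$l_m_index else NULL
}

#' Split a region at a profile position
#'
#' Cuts the region along the line through the split point perpendicular
#' to the sampled axis. Both sides must be nonempty, otherwise the split
#' is rejected and NULL returned.
#'
#' @param region a cell region.
#' @param split_index sample index into `profile` (from
#'   [detect_division()]).
#' @param profile the [axis_profile()] the index refers to.
#' @param axis axis the profile was taken along.
#' @return list of two cell regions (labels inherited; caller relabels),
#'   or NULL if the cut leaves an empty side.
#' @export
split_region <- function(region, split_index, profile,
                         axis = c("major", "minor")) {
  axis <- match.arg(axis)
  u <- if (axis == "major") region$major_axis else
    c(-region$major_axis[2], region$major_axis[1])
  s0 <- profile$positions[split_index]
  px <- region$centroid[["x"]] + s0 * u[1]
  py <- region$centroid[["y"]] + s0 * u[2]
  idx <- which(region$mask, arr.ind = TRUE)
  proj <- (idx[, 2] - px) * u[1] + (idx[, 1] - py) * u[2]
  a <- proj < 0
  if (!any(a) || all(a)) return(NULL)
  m1 <- matrix(FALSE, nrow(region$mask), ncol(region$mask))
  m2 <- m1
  m1[idx[a, , drop = FALSE]] <- TRUE
  m2[idx[!a, , drop = FALSE]] <- TRUE
  list(make_region(m1, region$label, region$frame, region$calibration),
       make_region(m2, region$label, region$frame, region$calibration))
}

#' Split an over-wide region transversely
#'
#' If the region's width strictly exceeds `r_w` (two cells lying side by
#' side merged into one object), a profile along the minor axis is
#' examined with the same local-minimum criterion and the region is cut
#' along the major axis at the detected position. Otherwise the region is
#' returned unchanged.
#'
#' @param region a cell region.
#' @param r_w width threshold in micrometres.
#' @param image inverted smoothed image (detector convention).
#' @param r_m septum threshold for the transverse profile.
#' @return list of one (unchanged) or two (split) cell regions.
#' @export
split_by_width <- function(region, r_w, image, r_m) {
  if (region$width_um <= r_w) return(list(region))
  prof <- axis_profile(region, image, axis = "minor")
  pos <- detect_division(prof, r_m)
  if (is.null(pos)) return(list(region))
  halves <- split_region(region, pos, prof, axis = "minor")
  if (is.null(halves)) return(list(region))
  halves
}

# split a region whose mask has physically separated into >= 2 components
# (post-division). Returns NULL unless the two largest components both
# look like complete cells (length >= min_len_um); fragments are not
# daughters.
split_components <- function(region, min_frac = 0.2, min_len_um = 0) {
  lab <- label_components(region$mask, 4L)
  ncomp <- max(lab)
  if (ncomp < 2L) return(NULL)
  sz <- tabulate(lab[lab > 0L])
  ord <- order(sz, decreasing = TRUE)
  if (sz[ord[2]] < min_frac * sum(sz)) return(NULL)
  out <- list()
  for (cid in ord[1:2]) {
    m <- lab == cid
    rg <- make_region(m, region$label, region$frame, region$calibration)
    if (rg$length_um < min_len_um) return(NULL)
    out[[length(out) + 1L]] <- rg
  }
  out
}
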