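# CellRegion: one segmented cell in one frame. A region is a list with the
# full-size logical mask plus derived shape descriptors. Lengths are the
# maximum Feret diameter of the mask (pole-to-pole extent of a rod), the
# width is area / length (accurate for high-aspect capsules), and the
# orientation comes from the second central moments.

#' Build a cell region from a mask
#'
#' @param mask logical matrix (full image size), nonempty.
#' @param label integer identity.
#' @param frame time index.
#' @param calibration micrometres per pixel.
#' @return an object of class `cell_region`: fields `label`, `frame`,
#'   `mask`, `contour` (ordered boundary pixels, columns x,y), `centroid`
#'   (x, y in px), `area` (px^2), `length_um`, `width_um`,
#'   `major_axis` (unit vector), `eccentricity`, `touches_border`, `bbox`.
#' @export
make_region <- function(mask, label = 1L, frame = 1L, calibration = 0.15) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("make_region: empty mask")
  y <- idx[, 1]; x <- idx[, 2]
  area <- nrow(idx)
  cx <- mean(x); cy <- mean(y)
  # second central moments (+1/12 pixel-extent correction)
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  eig <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  l1 <- max(eig$values[1], 1e-12); l2 <- max(eig$values[2], 1e-12)
  axis <- eig$vectors[, 1]
  if (axis[1] < 0) axis <- -axis
  ecc <- sqrt(max(0, 1 - l2 / l1))

  # pole-to-pole length: max pairwise distance between hull vertices
  bnd <- mask & !erode_mask(mask, 1L)
  bidx <- which(bnd, arr.ind = TRUE)
  pts <- cbind(x = bidx[, 2], y = bidx[, 1])
  if (nrow(pts) >= 3L) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(pts) >= 2L) {
    d2 <- as.matrix(stats::dist(pts))
    feret <- max(d2) + 1      # +1: pixel extent
  } else feret <- 1
  length_um <- feret * calibration
  width_um <- (area * calibration^2) / length_um

  # contour ordered by angle about the centroid (rods are convex enough)
  ang <- atan2(bidx[, 1] - cy, bidx[, 2] - cx)
  ord <- order(ang)
  contour <- cbind(x = bidx[ord, 2], y = bidx[ord, 1])

  nr <- nrow(mask); nc <- ncol(mask)
  touches <- any(idx[, 1] == 1L | idx[, 1] == nr |
                 idx[, 2] == 1L | idx[, 2] == nc)
  bbox <- c(rmin = min(y), rmax = max(y), cmin = min(x), cmax = max(x))
  structure(list(label = as.integer(label), frame = as.integer(frame),
                 mask = mask, contour = contour,
                 centroid = c(x = cx, y = cy), area = area,
                 length_um = length_um, width_um = width_um,
                 major_axis = axis, eccentricity = ecc,
                 touches_border = touches, bbox = bbox,
                 calibration = calibration),
            class = "cell_region")
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf(
    "cell_region label=%d frame=%d area=%d px^2 length=%.2f um width=%.2f um\n",
    x$label, x$frame, x$area, x$length_um, x$width_um))
  invisible(x)
}

# regions -> label matrix (pixel value = region label)
regions_to_labels <- function(regions, dims) {
  lab <- matrix(0L, dims[1], dims[2])
  for (r in regions) lab[r$mask] <- r$label
  lab
}

# crop window around a bbox with margin, clipped to the image
crop_window <- function(bbox, dims, margin) {
  r0 <- max(1L, bbox[["rmin"]] - margin)
  r1 <- min(dims[1], bbox[["rmax"]] + margin)
  c0 <- max(1L, bbox[["cmin"]] - margin)
  c1 <- min(dims[2], bbox[["cmax"]] + margin)
  list(rows = r0:r1, cols = c0:c1)
}
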