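# Synthetic time-lapse colonies of growing, dividing capsule (rod) cells
# with exact ground-truth masks and lineage. The simulator emulates the
# acquisition geometry of a microfluidic growth chamber experiment:
# calibration ~0.15 um/px, ~69 s frame interval, dark cells on a bright
# background, and a septum that brightens across the mid-axis as
# constriction progresses.
#
# Cell shape is a capsule: a rectangle of length L - W capped by two
# semicircles of diameter W, so the pole-to-pole extent is exactly L and
# the mask is analytic. Ground-truth division is recorded at the frame
# where septum progress reaches 1: the mother's last rendered state has
# progress < 1 and the two daughters (each ~L/2, separated by a 0.45 um
# gap along the mother axis) appear at the completion frame.

DIV_GAP_UM <- 0.45         # pole gap between newborn daughters:
                           # ~3 px at 0.15 um/px, so the division is
                           # optically resolvable like a real septum line
SEPTUM_HALFWIDTH_UM <- 0.08  # half-width of the rendered septum band

# distance between two segments (p1,p2) and (q1,q2), each a 2-vector
segseg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (a <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > tiny) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1; cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

cell_endpoints <- function(cell) {
  h <- max((cell$length - cell$width) / 2, 0)
  u <- c(cos(cell$angle), sin(cell$angle))
  list(a = c(cell$x, cell$y) - h * u, b = c(cell$x, cell$y) + h * u,
       u = u, h = h)
}

# surface-to-surface distance of two capsules (negative = overlap)
capsule_gap <- function(c1, c2) {
  e1 <- cell_endpoints(c1); e2 <- cell_endpoints(c2)
  segseg_dist(e1$a, e1$b, e2$a, e2$b) - (c1$width + c2$width) / 2
}

# iterative soft-body overlap resolution; cells are data.frame rows.
# Newborn sibling pairs keep the full division gap for a few frames
# (daughters push apart as they grow), so a fresh division stays
# optically resolvable even under crowding.
resolve_overlaps <- function(cells, min_gap, field_um, t = 1L,
                             n_iter = 40L) {
  n <- nrow(cells)
  sib_gap <- function(i, j) {
    if (!is.null(cells$sibling) && !is.na(cells$sibling[i]) &&
        cells$sibling[i] == cells$id[j] && t - cells$born[i] <= 3L)
      max(min_gap, 0.4)
    else min_gap
  }
  if (n >= 2L) {
    for (iter in seq_len(n_iter)) {
      moved <- FALSE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ci <- cells[i, ]; cj <- cells[j, ]
        gp <- capsule_gap(ci, cj)
        req <- sib_gap(i, j)
        if (gp < req) {
          d <- c(cj$x - ci$x, cj$y - ci$y)
          nd <- sqrt(sum(d * d))
          dir <- if (nd > 1e-9) d / nd else c(cos(i), sin(i))
          push <- (req - gp) / 2 + 1e-3
          cells$x[i] <- cells$x[i] - dir[1] * push
          cells$y[i] <- cells$y[i] - dir[2] * push
          cells$x[j] <- cells$x[j] + dir[1] * push
          cells$y[j] <- cells$y[j] + dir[2] * push
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  # keep capsules inside the field with a margin
  for (i in seq_len(n)) {
    e <- cell_endpoints(cells[i, ])
    half <- cells$width[i] / 2 + 0.4
    lo <- pmin(e$a, e$b) - half; hi <- pmax(e$a, e$b) + half
    shift <- c(0, 0)
    shift <- shift + pmax(0, -lo)        # push right/down if past 0
    shift <- shift - pmax(0, hi - field_um)
    cells$x[i] <- cells$x[i] + shift[1]
    cells$y[i] <- cells$y[i] + shift[2]
  }
  cells
}

#' Simulate a synthetic colony of rod cells
#'
#' Cells elongate exponentially (`L(t+1) = L(t) * exp(growth_rate)`). When
#' `L >= division_length` the cell enters a septum phase in which
#' `septum_progress` ramps linearly over `septum_frames` frames; at the
#' frame where progress reaches 1 the cell is replaced by two daughters of
#' length ~L/2 placed along the mother's axis. Overlaps are resolved by
#' soft-body repulsion so ground-truth masks are always disjoint. A fixed
#' seed gives a bit-identical scene.
#'
#' @param n_frames number of frames, >= 1.
#' @param seed integer seed; all randomness derives from it.
#' @param n_init number of initial cells (density / crowding control).
#' @param growth_rate per-frame exponential elongation rate, >= 0.
#' @param division_length length (um) that triggers septum formation; use
#'   `Inf` for non-dividing cells.
#' @param width cell diameter in um.
#' @param septum_frames frames over which the septum ramps to completion
#'   (>= 3).
#' @param calibration um per pixel.
#' @param image_size image dimensions in pixels, `c(rows, cols)`.
#' @param min_gap minimum surface gap (um) maintained between cells.
#' @param init_length optional fixed initial length (um) for all initial
#'   cells; by default lengths are drawn uniformly from 50-72% of the
#'   division length.
#' @param entries optional data.frame of scripted cell entries with
#'   columns `frame`, `x`, `y`, `angle`, `length` (um; `width` optional) —
#'   cells appearing mid-sequence as if entering the field of view.
#' @return an object of class `synthetic_scene`: `frames` (list of
#'   per-frame cell tables: id, parent, x, y, angle, length, width,
#'   septum), `lineage` (id, parent, b, d), `calibration`,
#'   `frame_interval`, `image_size`, `seed`, `params`.
#' @export
simulate_colony <- function(n_frames, seed = 1L, n_init = 3L,
                            growth_rate = 0.035, division_length = 6.5,
                            width = 1.0, septum_frames = 4L,
                            calibration = 0.15,
                            image_size = c(256L, 256L), min_gap = 0.2,
                            entries = NULL, frame_interval = 69,
                            init_length = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (growth_rate < 0) stop("growth_rate must be >= 0")
  if (any(image_size <= 0)) stop("image_size must be positive")
  if (septum_frames < 3) stop("septum_frames must be >= 3")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  field <- min(image_size) * calibration
  margin <- 2.5
  cells <- data.frame(
    id = seq_len(n_init), parent = NA_integer_,
    x = runif(n_init, margin, field - margin),
    y = runif(n_init, margin, field - margin),
    angle = runif(n_init, 0, pi),
    length = if (is.null(init_length))
      runif(n_init, 0.5, 0.72) * min(division_length, 6.5)
    else rep(init_length, n_init),
    width = width, septum = 0, sibling = NA_integer_, born = 1L)
  cells <- resolve_overlaps(cells, min_gap, field, 1L)
  next_id <- n_init + 1L
  birth <- stats::setNames(rep(1L, n_init), as.character(cells$id))
  parent_of <- stats::setNames(rep(NA_integer_, n_init),
                               as.character(cells$id))
  death <- integer(0)

  frames <- vector("list", n_frames)
  frames[[1]] <- cells
  t <- 1L
  while (t < n_frames) {
    t <- t + 1L
    # growth and septum progression
    cells$length <- cells$length * exp(growth_rate)
    start <- cells$septum == 0 & cells$length >= division_length
    cells$septum[cells$septum > 0] <-
      cells$septum[cells$septum > 0] + 1 / septum_frames
    cells$septum[start] <- 1 / septum_frames

    # divisions: progress reached 1
    div <- which(cells$septum >= 1 - 1e-9)
    if (length(div) > 0L) {
      kids <- list()
      for (i in div) {
        m <- cells[i, ]
        u <- c(cos(m$angle), sin(m$angle))
        dl <- (m$length - DIV_GAP_UM) / 2
        jit <- runif(2, -0.06, 0.06)
        for (k in 1:2) {
          sgn <- if (k == 1) -1 else 1
          sib <- if (k == 1) next_id + 1L else next_id - 1L
          kid <- data.frame(
            id = next_id, parent = m$id,
            x = m$x + sgn * u[1] * (dl + DIV_GAP_UM) / 2,
            y = m$y + sgn * u[2] * (dl + DIV_GAP_UM) / 2,
            angle = m$angle + jit[k], length = dl, width = m$width,
            septum = 0, sibling = sib, born = t)
          birth[as.character(next_id)] <- t
          parent_of[as.character(next_id)] <- m$id
          kids[[length(kids) + 1L]] <- kid
          next_id <- next_id + 1L
        }
        death[as.character(m$id)] <- t - 1L
      }
      cells <- rbind(cells[-div, , drop = FALSE], do.call(rbind, kids))
    }

    # scripted entries
    if (!is.null(entries)) {
      ent <- entries[entries$frame == t, , drop = FALSE]
      for (i in seq_len(nrow(ent))) {
        w <- if ("width" %in% names(ent)) ent$width[i] else width
        cells <- rbind(cells, data.frame(
          id = next_id, parent = NA_integer_, x = ent$x[i], y = ent$y[i],
          angle = ent$angle[i], length = ent$length[i], width = w,
          septum = 0, sibling = NA_integer_, born = t))
        birth[as.character(next_id)] <- t
        parent_of[as.character(next_id)] <- NA_integer_
        next_id <- next_id + 1L
      }
    }

    cells <- resolve_overlaps(cells, min_gap, field, t)
    rownames(cells) <- NULL
    frames[[t]] <- cells
  }

  ids <- as.integer(names(birth))
  lineage <- data.frame(
    id = ids,
    parent = unname(parent_of[as.character(ids)]),
    b = unname(birth[as.character(ids)]),
    d = vapply(as.character(ids), function(k)
      if (k %in% names(death)) as.integer(death[[k]])
      else as.integer(n_frames), integer(1)))
  structure(list(frames = frames, lineage = lineage,
                 calibration = calibration,
                 frame_interval = frame_interval,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 params = list(growth_rate = growth_rate,
                               division_length = division_length,
                               septum_frames = septum_frames,
                               min_gap = min_gap)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene: %d frames, %d cells total, %dx%d px @ %.3f um/px\n",
    length(x$frames), nrow(x$lineage), x$image_size[1], x$image_size[2],
    x$calibration))
  invisible(x)
}

# per-cell capsule geometry on the pixel grid, restricted to the bbox;
# returns pixel indices inside the capsule and their axial coordinate
capsule_pixels <- function(cell, dims, cal) {
  e <- cell_endpoints(cell)
  half <- cell$width / 2
  lo <- pmin(e$a, e$b) - half - 2 * cal
  hi <- pmax(e$a, e$b) + half + 2 * cal
  c0 <- max(1L, floor(lo[1] / cal)); c1 <- min(dims[2], ceiling(hi[1] / cal) + 1L)
  r0 <- max(1L, floor(lo[2] / cal)); r1 <- min(dims[1], ceiling(hi[2] / cal) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  px <- (rep(cols, each = length(rows)) - 0.5) * cal
  py <- (rep(rows, times = length(cols)) - 0.5) * cal
  dx <- px - cell$x; dy <- py - cell$y
  s <- dx * e$u[1] + dy * e$u[2]            # axial coordinate
  sc <- pmin(pmax(s, -e$h), e$h)            # clamped to the spine
  qx <- dx - sc * e$u[1]; qy <- dy - sc * e$u[2]
  d <- sqrt(qx^2 + qy^2)
  inside <- d <= half
  if (!any(inside)) return(NULL)
  ii <- rep(rows, times = length(cols))[inside]
  jj <- rep(cols, each = length(rows))[inside]
  list(idx = cbind(ii, jj), axial = s[inside], dist = d[inside])
}

#' Rasterize the ground-truth label mask of one frame
#'
#' @param scene a [simulate_colony()] scene.
#' @param t frame index.
#' @return integer label matrix; pixel value = cell id, 0 = background.
#' @export
scene_labels <- function(scene, t) {
  if (t < 1 || t > length(scene$frames))
    stop("frame index out of range: ", t)
  dims <- scene$image_size
  lab <- matrix(0L, dims[1], dims[2])
  cells <- scene$frames[[t]]
  for (i in seq_len(nrow(cells))) {
    cp <- capsule_pixels(cells[i, ], dims, scene$calibration)
    if (!is.null(cp)) lab[cp$idx] <- cells$id[i]
  }
  lab
}

#' Render one frame of a synthetic scene
#'
#' Rod interiors are darker than the background. A cell in septum phase
#' gains a transverse ridge at its mid-axis whose brightness rises toward
#' the background level with `septum_progress^2` (constriction becomes
#' optically apparent late), so the along-axis profile develops a local
#' extremum toward background as division approaches. The image is then
#' blurred and corrupted with additive Gaussian noise.
#'
#' @param scene a [simulate_colony()] scene.
#' @param t frame index.
#' @param noise_sd Gaussian noise standard deviation in gray levels.
#' @param blur_sd Gaussian blur standard deviation in pixels.
#' @param bg,fg background and cell-interior gray levels.
#' @param septum_contrast fraction of (bg - fg) the completed septum ridge
#'   reaches; < 1 keeps a noiseless rendering exactly thresholdable.
#' @return list with `image` (numeric matrix) and `labels` (exact
#'   ground-truth label matrix).
#' @export
render_frame <- function(scene, t, noise_sd = 3.6, blur_sd = 1,
                         bg = 200, fg = 80, septum_contrast = 0.9) {
  if (t < 1 || t > length(scene$frames))
    stop("frame index out of range: ", t)
  dims <- scene$image_size
  img <- matrix(bg * 1.0, dims[1], dims[2])
  lab <- matrix(0L, dims[1], dims[2])
  cells <- scene$frames[[t]]
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    cp <- capsule_pixels(cell, dims, scene$calibration)
    if (is.null(cp)) next
    lab[cp$idx] <- cell$id
    val <- rep(fg, nrow(cp$idx))
    if (cell$septum > 0) {
      ridge <- abs(cp$axial) <= SEPTUM_HALFWIDTH_UM
      val[ridge] <- fg + (cell$septum^2) * septum_contrast * (bg - fg)
    }
    img[cp$idx] <- val
  }
  if (blur_sd > 0) img <- smooth_image(img, blur_sd)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed((scene$seed %% 65536L) * 16384L + t)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), dims[1], dims[2])
  }
  list(image = img, labels = lab)
}

#' Render a whole scene
#'
#' @inheritParams render_frame
#' @return list with `images` and `labels`, each a list over frames.
#' @export
render_scene <- function(scene, noise_sd = 3.6, blur_sd = 1, bg = 200,
                         fg = 80, septum_contrast = 0.9) {
  n <- length(scene$frames)
  images <- vector("list", n); labels <- vector("list", n)
  for (t in seq_len(n)) {
    fr <- render_frame(scene, t, noise_sd, blur_sd, bg, fg,
                       septum_contrast)
    images[[t]] <- fr$image; labels[[t]] <- fr$labels
  }
  list(images = images, labels = labels)
}

#' Ground-truth track table of a scene
#'
#' @param scene a [simulate_colony()] scene.
#' @return data.frame with frame, id, parent, x_px, y_px (pixel centroid
#'   coordinates, 1-based), length_um, width_um, septum.
#' @export
gt_track_table <- function(scene) {
  out <- vector("list", length(scene$frames))
  for (t in seq_along(scene$frames)) {
    cells <- scene$frames[[t]]
    out[[t]] <- data.frame(
      frame = t, id = cells$id, parent = cells$parent,
      x_px = cells$x / scene$calibration + 0.5,
      y_px = cells$y / scene$calibration + 0.5,
      length_um = cells$length, width_um = cells$width,
      septum = cells$septum)
  }
  do.call(rbind, out)
}
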