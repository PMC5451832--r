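# Shared fixtures, built in code. Expensive renders are cached per test
# session.

.fixture_env <- new.env(parent = emptyenv())

cache_fixture <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# dark disk (value fg) of given radius on a bright background
disk_image <- function(n = 128, r = 30, ctr = c(n / 2, n / 2),
                       bg = 200, fg = 80) {
  d2 <- outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`)
  img <- matrix(bg, n, n)
  img[d2 <= r^2] <- fg
  img
}

disk_mask <- function(n = 128, r = 5, ctr = c(n / 2, n / 2)) {
  d2 <- outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`)
  d2 <= r^2
}

# signed distance to a centered circle
circle_sdf <- function(n, r, ctr = c((n + 1) / 2, (n + 1) / 2)) {
  d <- sqrt(outer((seq_len(n) - ctr[1])^2,
                  (seq_len(n) - ctr[2])^2, `+`))
  d - r
}

# a one-frame scene with explicitly placed cells (x, y in um)
manual_scene <- function(cells, image_size = c(128L, 128L),
                         calibration = 0.15) {
  structure(list(
    frames = list(cells), lineage = data.frame(
      id = cells$id, parent = rep(NA_integer_, nrow(cells)),
      b = rep(1L, nrow(cells)), d = rep(1L, nrow(cells))),
    calibration = calibration, frame_interval = 69,
    image_size = as.integer(image_size), seed = 1L,
    params = list()), class = "synthetic_scene")
}

manual_cells <- function(x, y, angle, length, width = 1, septum = 0) {
  n <- length(x)
  data.frame(id = seq_len(n), parent = rep(NA_integer_, n), x = x,
             y = y, angle = angle, length = length,
             width = rep(width, length.out = n),
             septum = rep(septum, length.out = n),
             sibling = rep(NA_integer_, n), born = rep(1L, n))
}

# maximum distance from the zero level set of phi to a true circle,
# using |phi| as the subpixel distance correction (|grad phi| ~ 1)
contour_hausdorff_vs_circle <- function(phi, ctr, r) {
  m <- phi < 0
  bnd <- m & !erode_mask(m, 1L)
  idx <- which(bnd, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2) +
    abs(phi[bnd])
  max(abs(rad - r))
}

# the standard 20-frame benchmark colony (acceptance criterion 4)
benchmark_eval <- function() {
  cache_fixture("benchmark42", {
    scene <- simulate_colony(20, seed = 42, n_init = 3)
    evaluate_on_scene(scene)
  })
}
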