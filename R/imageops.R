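# Low-level image operations shared by the segmentation and tracking
# modules. Images are numeric matrices [row, col].

# normalized 1-D Gaussian kernel truncated at 4 sigma (odd length)
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# normalized 1-D box kernel of odd side >= n
box_kernel <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  rep(1 / n, n)
}

#' Central-difference image gradient
#'
#' Gradient with replicated (Neumann) borders. `gx` is the derivative
#' along columns (x), `gy` along rows (y).
#'
#' @param img numeric matrix.
#' @return list with matrices `gx`, `gy` and `mag` (gradient magnitude).
#' @export
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  wj <- 1 / (jp - jm); wi <- 1 / (ip - im)
  gx <- sweep(img[, jp, drop = FALSE] - img[, jm, drop = FALSE], 2, wj, `*`)
  gy <- (img[ip, , drop = FALSE] - img[im, , drop = FALSE]) * wi
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Connected-component labelling
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 (default) or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 4L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cpp_label(m, as.integer(connectivity))
}

# binary erosion / dilation with a 3x3 cross, applied `n` times
shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

erode_mask <- function(mask, n = 1L) {
  m <- mask
  for (k in seq_len(n))
    m <- m & shift_mat(m, 1, 0, FALSE) & shift_mat(m, -1, 0, FALSE) &
      shift_mat(m, 0, 1, FALSE) & shift_mat(m, 0, -1, FALSE)
  m
}

dilate_mask <- function(mask, n = 1L) {
  m <- mask
  for (k in seq_len(n))
    m <- m | shift_mat(m, 1, 0, FALSE) | shift_mat(m, -1, 0, FALSE) |
      shift_mat(m, 0, 1, FALSE) | shift_mat(m, 0, -1, FALSE)
  m
}

# ring of pixels around the boundary of a mask (1 px inside + 1 px outside)
boundary_band <- function(mask) {
  dilate_mask(mask, 1L) & !erode_mask(mask, 1L)
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a 256-bin histogram. Used to
#' separate boundary from interior sub-windows by their maximum gradient.
#'
#' @param x numeric vector.
#' @return threshold value; values > threshold belong to the upper class.
#' @export
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) < 1e-12) return(max(x, -Inf))
  nb <- 256L
  br <- seq(min(x), max(x), length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nb)
  w <- cumsum(h); mu <- cumsum(h * seq_len(nb))
  tot <- w[nb]; mtot <- mu[nb]
  w1 <- w[-nb]; w2 <- tot - w1
  m1 <- mu[-nb] / pmax(w1, 1); m2 <- (mtot - mu[-nb]) / pmax(w2, 1)
  bc <- w1 * w2 * (m1 - m2)^2
  bc[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(bc)
  0.5 * (br[k] + br[k + 1L])
}

# bilinear interpolation of img at (x = col, y = row), 1-based coordinates
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  j0 <- pmin(floor(x), nc - 1L); i0 <- pmin(floor(y), nr - 1L)
  fx <- x - j0; fy <- y - i0
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    img[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    img[cbind(i0 + 1, j0 + 1)] * fx * fy
}
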