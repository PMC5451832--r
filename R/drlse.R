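# Distance-regularized level set evolution (DRLSE): energy terms, gradient
# flow, and the three-term stopping criterion. The level set phi is a
# numeric matrix over the image domain; the contour is its zero level set
# and the cell interior is phi < 0.

#' Gaussian smoothing
#'
#' Convolution with a normalized Gaussian kernel (truncated at 4 sigma),
#' separable implementation, replicate padding. `sigma = 0` returns the
#' input unchanged.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels, >= 0.
#' @return smoothed matrix of the same shape.
#' @export
smooth_image <- function(image, sigma = 1) {
  stopifnot(is.matrix(image), sigma >= 0)
  if (sigma == 0) return(image)
  cpp_conv_sep(image, gaussian_kernel(sigma))
}

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in flat regions and
#' small at strong intensity edges, where the contour should stop.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return matrix `g` with values in (0, 1].
#' @export
edge_indicator <- function(image, sigma = 1) {
  sm <- smooth_image(image, sigma)
  1 / (1 + image_gradient(sm)$mag^2)
}

#' Double-well potential of the distance regularizer
#'
#' `p(s) = (1/(2*pi)^2) (1 - cos(2*pi*s))` for `s <= 1` and
#' `(s - 1)^2 / 2` for `s > 1`; minima at s = 0 and s = 1 keep
#' `|grad phi|` near 1 (a signed distance function) without
#' reinitialization.
#'
#' @param s nonnegative numeric vector.
#' @return p(s), vectorized.
#' @export
double_well_p <- function(s) {
  if (any(s < 0)) stop("double_well_p: s must be nonnegative")
  ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, 0.5 * (s - 1)^2)
}

#' Derivative ratio d_p(s) = p'(s) / s
#'
#' The removable singularity at s = 0 is filled with its limit 1. Bounded:
#' `|d_p(s)| <= 1` for all s >= 0.
#'
#' @param s nonnegative numeric vector.
#' @return d_p(s), vectorized.
#' @export
d_p <- function(s) {
  if (any(s < 0)) stop("d_p: s must be nonnegative")
  out <- ifelse(s <= 1,
                ifelse(s < 1e-12, 1, sin(2 * pi * s) / (2 * pi * s)),
                (s - 1) / s)
  out
}

#' Unweighted DRLSE energy terms
#'
#' The three integrals of the DRLSE energy: the distance-regularization
#' term Rp, the weighted contour length Lg (line integral of `g` along the
#' zero level set, via the smoothed Dirac delta) and the weighted interior
#' area Ag (integral of `g` over `phi < 0`, via the smoothed Heaviside).
#'
#' @param phi level set matrix.
#' @param g edge indicator matrix, same shape.
#' @param eps Dirac/Heaviside half-width in pixels.
#' @return list with numbers `Rp`, `Lg`, `Ag`.
#' @export
energy_terms <- function(phi, g, eps = 1.5) {
  if (!identical(dim(phi), dim(g)))
    stop("energy_terms: phi and g shapes differ")
  v <- cpp_energy_terms(phi, g, eps)
  list(Rp = v[["Rp"]], Lg = v[["Lg"]], Ag = v[["Ag"]])
}

#' Stopping criterion increment
#'
#' Squared change of the three energy terms between successive iterations:
#' `delta = (Rp_i - Rp_{i-1})^2 + (Lg_i - Lg_{i-1})^2 + (Ag_i - Ag_{i-1})^2`.
#' Evolution halts when `delta <= K`; `K = 0` halts only at an exact
#' steady state.
#'
#' @param prev,cur energy term lists as returned by [energy_terms()].
#' @return scalar delta.
#' @export
stopping_delta <- function(prev, cur) {
  (cur$Rp - prev$Rp)^2 + (cur$Lg - prev$Lg)^2 + (cur$Ag - prev$Ag)^2
}

#' Binary-step level set initialization
#'
#' `-c0` inside the seed mask, `+c0` outside. DRLSE accepts such
#' non-distance initializations; the regularizer restores the signed
#' distance profile during evolution.
#'
#' @param mask logical matrix of seed interior.
#' @param c0 step height.
#' @return level set matrix.
#' @export
phi_init <- function(mask, c0 = 2) {
  ifelse(mask, -c0, c0) * 1.0
}

#' DRLSE gradient flow
#'
#' Iterates
#' `phi <- phi + dt * (mu * div(d_p(|grad phi|) grad phi)
#'   + lam * delta_eps(phi) * div(g grad phi / |grad phi|)
#'   + alpha * g * delta_eps(phi))`
#' until the stopping increment ([stopping_delta()]) drops below
#' `params$K` or `params$max_iter` is reached. Central differences,
#' 5-point divergence, Neumann boundary handling, `|grad phi|` floored at
#' 1e-10 in the curvature term.
#'
#' @param phi level set matrix (e.g. from [phi_init()]).
#' @param g edge indicator matrix, same shape.
#' @param params a [drlse_params()] object.
#' @param freeze_mask optional logical matrix; where TRUE the level set is
#'   held fixed (used for non-overlap coevolution of neighbouring cells).
#' @return list with `phi` (final field), `iterations` (updates
#'   performed), `energies` (matrix of Rp/Lg/Ag per evaluated state,
#'   initial state first) and `deltas` (stopping increments).
#' @export
evolve <- function(phi, g, params = drlse_params(), freeze_mask = NULL) {
  stopifnot(inherits(params, "drlse_params"))
  if (!identical(dim(phi), dim(g)))
    stop("evolve: phi and g shapes differ")
  if (is.null(freeze_mask)) {
    fr <- matrix(0L, 0, 0)
  } else {
    if (!identical(dim(freeze_mask), dim(phi)))
      stop("evolve: freeze_mask shape differs from phi")
    fr <- matrix(as.integer(freeze_mask != 0), nrow(phi), ncol(phi))
  }
  cpp_drlse_evolve(phi, g, params$mu, params$lam, params$alpha,
                   params$dt, params$eps, params$K, params$max_iter, fr)
}
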