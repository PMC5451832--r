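#' DRLSE evolution parameters
#'
#' Parameters of the distance-regularized level set evolution and its
#' stopping criterion. Defaults are the selected configuration of the
#' method: time step 1, regularizer weight 0.2, length weight 5, area
#' weight -3 (negative to expand contours) and stopping tolerance 0.005.
#' The smoothed Dirac/Heaviside half-width `eps` and the binary-step
#' initialization height `c0` are conventional discretization choices.
#'
#' @param mu weight of the distance-regularization term; must satisfy
#'   `mu * dt < 0.25` for stability.
#' @param lam weight of the weighted-length (edge) term, > 0.
#' @param alpha weight of the weighted-area term; negative values expand
#'   the contour.
#' @param dt time step of the gradient flow, > 0.
#' @param K stopping tolerance on the squared change of the three energy
#'   terms between successive iterations; 0 halts only at steady state.
#' @param sigma standard deviation (pixels) of the Gaussian used for
#'   preprocessing and the edge indicator.
#' @param eps half-width (pixels) of the smoothed Dirac/Heaviside.
#' @param c0 height of the binary-step level set initialization.
#' @param max_iter iteration cap of the evolution.
#' @return an object of class `drlse_params`.
#' @export
drlse_params <- function(mu = 0.2, lam = 5, alpha = -3, dt = 1,
                         K = 0.005, sigma = 1, eps = 1.5, c0 = 2,
                         max_iter = 400) {
  stopifnot(mu > 0, lam > 0, dt > 0, K >= 0, eps > 0, c0 > 0,
            max_iter >= 1, sigma >= 0)
  if (mu * dt >= 0.25)
    stop("unstable configuration: require mu * dt < 0.25 (got ",
         mu * dt, ")")
  structure(list(mu = mu, lam = lam, alpha = alpha, dt = dt, K = K,
                 sigma = sigma, eps = eps, c0 = c0, max_iter = max_iter),
            class = "drlse_params")
}

#' Segmentation configuration
#'
#' @param r_s minimum size (major-axis length, micrometres) of a complete
#'   cell; smaller final components are discarded as debris. Default 3.
#' @param calibration pixel size, micrometres per pixel.
#' @param thr_window side (pixels) of the local-mean window of the adaptive
#'   threshold used for seeding.
#' @param thr_offset gray-level offset subtracted from the local mean; a
#'   pixel seeds a cell when it is darker than `local mean - thr_offset`. Default 30: about half the
#'   cell-to-background contrast of an 8-bit phase-contrast-like image,
#'   which puts the seed boundary at the 50% edge crossing.
#' @param min_seed_area minimum seed component area in pixels.
#' @param remove_border drop final regions touching the image border
#'   (applies to first-frame segmentation and new-cell capture).
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(r_s = 3, calibration = 0.15, thr_window = 25,
                       thr_offset = 30, min_seed_area = 9,
                       remove_border = TRUE) {
  stopifnot(r_s > 0, calibration > 0, thr_window >= 3, min_seed_area >= 1)
  structure(list(r_s = r_s, calibration = calibration,
                 thr_window = thr_window, thr_offset = thr_offset,
                 min_seed_area = min_seed_area,
                 remove_border = remove_border),
            class = "seg_config")
}

#' Tracking configuration
#'
#' Defaults follow the selected configuration of the method: sub-window
#' side `w` = 0.6 um, septum threshold multiplier `tau` = 1.2, width
#' threshold `r_w` = 1.2 um, and trajectory-energy weights
#' (beta, gamma, eta) = (0.02, 0.5, 0.5).
#'
#' @param w sub-window side in micrometres used to split a propagated
#'   region into small windows.
#' @param tau septum threshold multiplier: the division threshold is
#'   `r_m = mean + tau * sd` of the tracked contours' boundary-band
#'   intensities in the current frame.
#' @param r_w width threshold in micrometres; wider regions are candidates
#'   for a transverse split, and `r_w` (in pixels) also scales the
#'   exclusion energy.
#' @param beta,gamma,eta weights of the velocity, exclusion and
#'   regularization terms of the trajectory energy.
#' @param lookahead frames over which ambiguous assignments are considered;
#'   the implementation resolves assignments online (effective value 1).
#' @param max_enum cap on enumerated assignments of one ambiguous
#'   component before falling back to greedy maximum overlap.
#' @param min_div_len_factor septum detection runs only on regions whose
#'   length exceeds `min_div_len_factor * r_s`; prevents spurious splits
#'   of newborn cells.
#' @return an object of class `track_config`.
#' @export
track_config <- function(w = 0.6, tau = 1.2, r_w = 1.2, beta = 0.02,
                         gamma = 0.5, eta = 0.5, lookahead = 3,
                         max_enum = 64, min_div_len_factor = 2) {
  stopifnot(w > 0, r_w > 0, beta >= 0, gamma >= 0, eta >= 0,
            lookahead >= 1, max_enum >= 1)
  structure(list(w = w, tau = tau, r_w = r_w, beta = beta, gamma = gamma,
                 eta = eta, lookahead = lookahead, max_enum = max_enum,
                 min_div_len_factor = min_div_len_factor),
            class = "track_config")
}

#' Full pipeline configuration
#'
#' Bundles the DRLSE, segmentation and tracking parameter groups with the
#' acquisition metadata. Every default equals the method's selected value
#' where one exists.
#'
#' @param calibration micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param seed integer seed for any stochastic component.
#' @param drlse a [drlse_params()] object.
#' @param seg a [seg_config()] object (its calibration is overridden by
#'   `calibration`).
#' @param track a [track_config()] object.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(calibration = 0.15, frame_interval = 69,
                            seed = 1L, drlse = drlse_params(),
                            seg = seg_config(calibration = calibration),
                            track = track_config()) {
  stopifnot(calibration > 0, frame_interval > 0)
  seg$calibration <- calibration
  structure(list(calibration = calibration,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 drlse = drlse, seg = seg, track = track),
            class = "pipeline_config")
}

# flatten a pipeline_config to a named list of scalars (for run logs)
config_flatten <- function(cfg) {
  out <- list(calibration = cfg$calibration,
              frame_interval = cfg$frame_interval, seed = cfg$seed)
  for (grp in c("drlse", "seg", "track"))
    for (nm in names(cfg[[grp]]))
      out[[paste(grp, nm, sep = ".")]] <- cfg[[grp]][[nm]]
  out
}
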