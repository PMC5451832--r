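# Trajectories, the tracking state, the global trajectory energy and the
# optimal assignment of segmented regions to trajectories.
#
# A trajectory is one cell's identity from its birth frame b to its final
# frame d, with its per-frame centroid positions (the state vector X) and
# parent/children links created at divisions.

#' Create a trajectory
#'
#' @param id integer identity.
#' @param b birth frame.
#' @param positions numeric matrix (frames x 2, columns x,y) of centroids
#'   for frames b..d.
#' @param parent parent trajectory id or NA.
#' @return an object of class `trajectory` with fields `id`, `b`, `d`,
#'   `positions`, `regions` (list keyed by frame), `parent`, `children`.
#' @export
new_trajectory <- function(id, b, positions, parent = NA_integer_) {
  positions <- matrix(positions, ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  structure(list(id = as.integer(id), b = as.integer(b),
                 d = as.integer(b) + nrow(positions) - 1L,
                 positions = positions, regions = list(),
                 parent = as.integer(parent), children = NULL),
            class = "trajectory")
}

traj_length <- function(tr) tr$d - tr$b + 1L   # F(n)

traj_pos_at <- function(tr, t) {
  if (t < tr$b || t > tr$d) return(NULL)
  tr$positions[t - tr$b + 1L, ]
}

#' Create a tracking state
#'
#' @param trajectories list of [new_trajectory()] objects.
#' @param n_frames total number of frames F.
#' @param calibration micrometres per pixel.
#' @return an object of class `tracking_state`.
#' @export
tracking_state <- function(trajectories = list(), n_frames = 0L,
                           calibration = 0.15) {
  names(trajectories) <- vapply(trajectories, function(tr)
    as.character(tr$id), character(1))
  structure(list(trajectories = trajectories,
                 n_frames = as.integer(n_frames),
                 calibration = calibration),
            class = "tracking_state")
}

#' @export
print.tracking_state <- function(x, ...) {
  cat(sprintf("tracking_state: %d trajectories over %d frames\n",
              length(x$trajectories), x$n_frames))
  invisible(x)
}

#' Constant-velocity energy
#'
#' `E_vel = sum_n sum_{t=b_n}^{d_n-2} || X_n^t - 2 X_n^{t+1} + X_n^{t+2} ||^2`
#' — the squared discrete acceleration of every trajectory; trajectories
#' shorter than 3 frames contribute 0.
#'
#' @param state a [tracking_state()].
#' @return scalar.
#' @export
energy_vel <- function(state) {
  tot <- 0
  for (tr in state$trajectories) {
    p <- tr$positions
    if (nrow(p) < 3L) next
    acc <- p[1:(nrow(p) - 2), , drop = FALSE] -
      2 * p[2:(nrow(p) - 1), , drop = FALSE] +
      p[3:nrow(p), , drop = FALSE]
    tot <- tot + sum(acc^2)
  }
  tot
}

#' Exclusion energy
#'
#' `E_exc = sum_t sum_{n, j != n} r_w^2 / || X_n^t - X_j^t ||^2` over the
#' ordered pairs of cells alive at each frame; penalizes configurations
#' in which cells come too close. Coincident positions yield `Inf`
#' (the assignment is rejected rather than propagating infinities).
#'
#' @param state a [tracking_state()].
#' @param r_w minimum average cell width in pixels.
#' @return scalar (possibly `Inf`).
#' @export
energy_exc <- function(state, r_w) {
  trs <- state$trajectories
  if (length(trs) < 2L) return(0)
  frames <- unique(unlist(lapply(trs, function(tr) tr$b:tr$d)))
  tot <- 0
  for (t in frames) {
    pos <- do.call(rbind, lapply(trs, function(tr) traj_pos_at(tr, t)))
    if (is.null(pos) || nrow(pos) < 2L) next
    d2 <- as.matrix(stats::dist(pos))^2
    off <- d2[upper.tri(d2)]
    if (any(off < 1e-12)) return(Inf)
    tot <- tot + 2 * sum(r_w^2 / off)   # ordered pairs
  }
  tot
}

#' Regularization energy
#'
#' `E_reg = N + sum_n 1 / F(n)`: favours few, long trajectories.
#'
#' @param state a [tracking_state()].
#' @return scalar.
#' @export
energy_reg <- function(state) {
  trs <- state$trajectories
  if (length(trs) == 0L) return(0)
  length(trs) + sum(vapply(trs, function(tr) 1 / traj_length(tr),
                           numeric(1)))
}

#' Total trajectory energy
#'
#' `E(X) = beta E_vel + gamma E_exc + eta E_reg` with the configured
#' weights; `r_w` is converted from micrometres to pixels with the
#' state's calibration.
#'
#' @param state a [tracking_state()].
#' @param cfg a [track_config()].
#' @return scalar.
#' @export
energy_total <- function(state, cfg = track_config()) {
  r_w_px <- cfg$r_w / state$calibration
  cfg$beta * energy_vel(state) + cfg$gamma * energy_exc(state, r_w_px) +
    cfg$eta * energy_reg(state)
}

# ---- assignment --------------------------------------------------------

mask_overlap <- function(a, b) sum(a & b)

# enumerate injective assignments of candidates (indices) to options;
# each candidate may also open a new trajectory (option 0)
enumerate_assignments <- function(options, cap) {
  out <- list(integer(0))
  for (opts in options) {
    nxt <- list()
    for (partial in out)
      for (o in c(opts[!(opts %in% partial)], 0L)) {
        nxt[[length(nxt) + 1L]] <- c(partial, o)
        if (length(nxt) > cap) return(NULL)
      }
    out <- nxt
    if (length(out) > cap) return(NULL)
  }
  out
}

#' Optimal assignment of candidate regions to trajectories
#'
#' Unambiguous links (one region overlapping exactly one live trajectory
#' and vice versa) are accepted directly. For ambiguous components all
#' consistent assignments (each region to one of its overlapping
#' trajectories, or to a new trajectory; each trajectory extended by at
#' most one region) are enumerated and the one minimizing the total
#' trajectory energy over the affected trajectories is chosen; beyond
#' `cfg$max_enum` enumerable assignments the component falls back to
#' greedy maximum overlap. Division items terminate the mother at t-1 and
#' open two child trajectories. Every region ends up in exactly one
#' trajectory.
#'
#' @param state the [tracking_state()] up to frame t-1.
#' @param items list of candidate items for frame t. Each item is a list
#'   with either `region` and `src` (source trajectory id, or NA for a
#'   fresh detection), or — for a division — `regions` (two daughters),
#'   `src` (mother id) and `division = TRUE`.
#' @param t current frame index.
#' @param cfg a [track_config()].
#' @return the updated `tracking_state` (with an attribute
#'   `frame_regions`: the regions of frame t relabelled by trajectory id).
#' @export
assign_optimal <- function(state, items, t, cfg = track_config()) {
  trs <- state$trajectories
  next_id <- if (length(trs) > 0L)
    max(vapply(trs, `[[`, integer(1), "id")) + 1L else 1L
  frame_regions <- list()

  live_ids <- names(trs)[vapply(trs, function(tr) tr$d == t - 1L,
                                logical(1))]
  extend <- function(id, region) {
    tr <- trs[[as.character(id)]]
    tr$positions <- rbind(tr$positions, region$centroid)
    tr$d <- t
    region$label <- tr$id
    tr$regions[[as.character(t)]] <- region
    trs[[as.character(id)]] <<- tr
    frame_regions[[length(frame_regions) + 1L]] <<- region
  }
  open_new <- function(region, parent = NA_integer_) {
    tr <- new_trajectory(next_id, t, matrix(region$centroid, 1),
                         parent = parent)
    region$label <- tr$id
    tr$regions[[as.character(t)]] <- region
    trs[[as.character(next_id)]] <<- tr
    frame_regions[[length(frame_regions) + 1L]] <<- region
    next_id <<- next_id + 1L
    tr$id
  }

  # divisions first: close the mother, open two children
  for (it in items) {
    if (!isTRUE(it$division)) next
    mid <- as.character(it$src)
    kid_ids <- c(open_new(it$regions[[1]], parent = it$src),
                 open_new(it$regions[[2]], parent = it$src))
    if (!is.null(trs[[mid]])) trs[[mid]]$children <- kid_ids
    live_ids <- setdiff(live_ids, mid)
  }

  plain <- Filter(function(it) !isTRUE(it$division), items)
  if (length(plain) > 0L) {
    # overlap links against the live trajectories' t-1 masks
    links <- vector("list", length(plain))
    for (k in seq_along(plain)) {
      it <- plain[[k]]
      ov <- integer(0)
      for (id in live_ids) {
        prev <- trs[[id]]$regions[[as.character(t - 1L)]]
        hit <- if (!is.null(prev))
          mask_overlap(prev$mask, it$region$mask) > 0L
        else identical(as.integer(id), as.integer(it$src))
        if (hit) ov <- c(ov, as.integer(id))
      }
      if (!is.na(it$src) && !(as.integer(it$src) %in% ov) &&
          as.character(it$src) %in% live_ids)
        ov <- c(ov, as.integer(it$src))
      links[[k]] <- ov
    }
    # bipartite connected components over shared trajectory links
    comp <- seq_along(plain)
    repeat {
      changed <- FALSE
      for (i in seq_along(plain)) for (j in seq_along(plain))
        if (i < j && length(intersect(links[[i]], links[[j]])) > 0L &&
            comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      ks <- which(comp == cc)
      opt <- links[ks]
      if (all(lengths(opt) <= 1L) &&
          !anyDuplicated(unlist(opt))) {
        for (k in ks) {
          if (length(links[[k]]) == 1L) extend(links[[k]], plain[[k]]$region)
          else open_new(plain[[k]]$region)
        }
        next
      }
      assigns <- enumerate_assignments(opt, cfg$max_enum)
      if (is.null(assigns)) {
        # greedy fallback: maximum overlap first
        taken <- integer(0)
        ord <- ks[order(vapply(ks, function(k)
          -max(c(0, vapply(links[[k]], function(id) {
            prev <- trs[[as.character(id)]]$regions[[as.character(t - 1L)]]
            if (is.null(prev)) 0L else
              mask_overlap(prev$mask, plain[[k]]$region$mask)
          }, integer(1)))), numeric(1)))]
        for (k in ord) {
          free <- setdiff(links[[k]], taken)
          if (length(free) > 0L) {
            best <- free[which.max(vapply(free, function(id) {
              prev <- trs[[as.character(id)]]$regions[[as.character(t - 1L)]]
              if (is.null(prev)) 0L else
                mask_overlap(prev$mask, plain[[k]]$region$mask)
            }, integer(1)))]
            extend(best, plain[[k]]$region); taken <- c(taken, best)
          } else open_new(plain[[k]]$region)
        }
        next
      }
      # exact: minimize the trajectory energy over the affected tracks
      affected <- as.character(unique(unlist(opt)))
      best_a <- NULL; best_e <- Inf
      for (a in assigns) {
        mini <- trs[affected]
        extra <- 0L
        ok <- TRUE
        for (q in seq_along(ks)) {
          id <- a[q]
          reg <- plain[[ks[q]]]$region
          if (id == 0L) { extra <- extra + 1L; next }
          tr <- mini[[as.character(id)]]
          if (is.null(tr) || tr$d != t - 1L) { ok <- FALSE; break }
          tr$positions <- rbind(tr$positions, reg$centroid)
          tr$d <- t
          mini[[as.character(id)]] <- tr
        }
        if (!ok) next
        ms <- tracking_state(unname(mini), state$n_frames,
                             state$calibration)
        e <- energy_total(ms, cfg) + cfg$eta * extra * (1 + 1)
        if (e < best_e) { best_e <- e; best_a <- a }
      }
      if (is.null(best_a)) best_a <- rep(0L, length(ks))
      for (q in seq_along(ks)) {
        if (best_a[q] == 0L) open_new(plain[[ks[q]]]$region)
        else extend(best_a[q], plain[[ks[q]]]$region)
      }
    }
  }

  out <- tracking_state(unname(trs), max(state$n_frames, t),
                        state$calibration)
  attr(out, "frame_regions") <- frame_regions
  out
}
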