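# Lineage trees and single-cell growth statistics.

#' Build a lineage tree from a tracking state
#'
#' Validates the parent/children links and returns the binary forest of
#' mother/daughter relations with generation numbers (root = 0).
#'
#' @param state a [tracking_state()] (or a [track_stack()] result).
#' @return an object of class `lineage_tree`: `nodes` (data.frame id,
#'   parent, b, d, generation, children as list-column) and `roots`.
#' @export
build_tree <- function(state) {
  if (!inherits(state, "tracking_state") && !is.null(state$state))
    state <- state$state
  trs <- state$trajectories
  ids <- unname(vapply(trs, `[[`, integer(1), "id"))
  bad <- character(0)
  for (tr in trs) {
    if (!is.na(tr$parent)) {
      p <- trs[[as.character(tr$parent)]]
      if (is.null(p)) {
        bad <- c(bad, sprintf("%d: missing parent %d", tr$id, tr$parent))
      } else {
        if (tr$b != p$d + 1L)
          bad <- c(bad, sprintf("%d: b=%d but parent %d ends at %d",
                                tr$id, tr$b, p$id, p$d))
        if (is.null(p$children) || !(tr$id %in% p$children))
          bad <- c(bad, sprintf("%d: not among children of %d",
                                tr$id, p$id))
      }
    }
    if (!is.null(tr$children) && length(tr$children) != 2L)
      bad <- c(bad, sprintf("%d: %d children (must be 0 or 2)", tr$id,
                            length(tr$children)))
  }
  if (length(bad) > 0L)
    stop("inconsistent lineage: ", paste(bad, collapse = "; "))

  gen <- stats::setNames(rep(NA_integer_, length(ids)),
                         as.character(ids))
  depth <- function(id) {
    k <- as.character(id)
    if (!is.na(gen[[k]])) return(gen[[k]])
    p <- trs[[k]]$parent
    g <- if (is.na(p)) 0L else depth(p) + 1L
    gen[[k]] <<- g
    g
  }
  for (id in ids) depth(id)
  nodes <- data.frame(
    id = ids,
    parent = vapply(trs, function(tr) tr$parent, integer(1)),
    b = vapply(trs, `[[`, integer(1), "b"),
    d = vapply(trs, `[[`, integer(1), "d"),
    generation = unname(gen[as.character(ids)]), row.names = NULL)
  nodes$children <- lapply(trs, function(tr)
    if (is.null(tr$children)) integer(0) else tr$children)
  structure(list(nodes = nodes, roots = ids[is.na(nodes$parent)]),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d nodes, %d roots, max generation %d\n",
              nrow(x$nodes), length(x$roots), max(x$nodes$generation)))
  invisible(x)
}

#' Newick export of a lineage tree
#'
#' Branch lengths are trajectory durations F(n) in frames; one Newick
#' string per root.
#'
#' @param tree a [build_tree()] lineage tree.
#' @return character vector of Newick strings.
#' @export
lineage_newick <- function(tree) {
  nd <- tree$nodes
  rec <- function(id) {
    row <- nd[nd$id == id, ]
    len <- row$d - row$b + 1L
    kids <- row$children[[1]]
    if (length(kids) == 0L) sprintf("%d:%d", id, len)
    else sprintf("(%s,%s)%d:%d", rec(kids[1]), rec(kids[2]), id, len)
  }
  vapply(tree$roots, function(r) paste0(rec(r), ";"), character(1))
}

#' Single-cell growth statistics
#'
#' Per trajectory: size at birth and at division (pole-to-pole length,
#' micrometres), division time (frames, and seconds via the frame
#' interval), and the elongation rate fitted as the least-squares slope
#' of log(length) against frame. Trajectories shorter than 3 frames or
#' with non-positive lengths are skipped with a warning.
#'
#' @param result a [track_stack()] result (or a tracking_state whose
#'   trajectories carry regions).
#' @param frame_interval seconds between frames.
#' @return data.frame with id, size_at_birth, size_at_division,
#'   divides (TRUE when the trajectory ends in a division),
#'   division_time_frames, division_time_s, elongation_rate (per frame)
#'   and elongation_rate_per_hour.
#' @export
growth_curves <- function(result, frame_interval = 69) {
  state <- if (inherits(result, "tracking_state")) result else
    result$state
  rows <- list()
  for (tr in state$trajectories) {
    frames <- sort(as.integer(names(tr$regions)))
    if (length(frames) < 3L) next
    len <- vapply(as.character(frames), function(k)
      tr$regions[[k]]$length_um, numeric(1))
    if (any(!is.finite(len)) || any(len <= 0)) {
      warning("trajectory ", tr$id, ": non-positive length, skipped")
      next
    }
    fit <- stats::lm(log(len) ~ frames)
    rate <- unname(stats::coef(fit)[2])
    divides <- !is.null(tr$children)
    Fn <- traj_length(tr)
    rows[[length(rows) + 1L]] <- data.frame(
      id = tr$id, size_at_birth = len[1],
      size_at_division = len[length(len)], divides = divides,
      division_time_frames = if (divides) Fn else NA_integer_,
      division_time_s = if (divides) Fn * frame_interval else NA_real_,
      elongation_rate = rate,
      elongation_rate_per_hour = rate * 3600 / frame_interval)
  }
  if (length(rows) == 0L)
    return(data.frame(id = integer(0), size_at_birth = numeric(0),
                      size_at_division = numeric(0), divides = logical(0),
                      division_time_frames = integer(0),
                      division_time_s = numeric(0),
                      elongation_rate = numeric(0),
                      elongation_rate_per_hour = numeric(0)))
  do.call(rbind, rows)
}
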