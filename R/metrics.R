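# Evaluation: Dice coefficient, segmentation outcome categories
# (TP / over-segmentation / under-segmentation / FN), MOTP and MOTA.

#' Dice coefficient
#'
#' `2 |A ∩ B| / (|A| + |B|)` between two binary masks; two empty masks
#' have Dice 1 by convention.
#'
#' @param A,B logical matrices of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("dice: shape mismatch")
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0L) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Classify segmentation outcomes
#'
#' Builds a bipartite overlap graph between ground-truth and predicted
#' objects (links where IoU >= `iou_min` or where the intersection covers
#' at least half of either object) and classifies every ground-truth
#' cell: a 1-1 link is a true positive, one gt linked to k >= 2
#' predictions is over-segmented, k >= 2 gt linked to one prediction are
#' under-segmented, an unlinked gt is a false negative. A gt cell listed
#' in `division_labels` (cells undergoing division in this frame) counts
#' as TP when matched by either one or two predictions — methods
#' differ in when they call a dividing cell one or two objects, so
#' neither is wrong.
#'
#' @param pred,gt integer label masks (0 = background).
#' @param iou_min IoU threshold for a confident 1-1 match.
#' @param division_labels integer vector of gt labels under the division
#'   leniency rule.
#' @return list with counts `TP`, `over_seg`, `under_seg`, `FN` (all in
#'   ground-truth cells), `n_gt`, `accuracy` (% of gt cells that are TP)
#'   and `dice_per_cell` (named Dice of each matched gt cell).
#' @export
classify_segmentation <- function(pred, gt, iou_min = 0.5,
                                  division_labels = integer(0)) {
  if (!identical(dim(pred), dim(gt)))
    stop("classify_segmentation: shape mismatch")
  gt_ids <- sort(setdiff(unique(as.vector(gt)), 0L))
  pr_ids <- sort(setdiff(unique(as.vector(pred)), 0L))
  n_gt <- length(gt_ids)
  if (n_gt == 0L)
    return(list(TP = 0L, over_seg = 0L, under_seg = 0L, FN = 0L,
                n_gt = 0L, accuracy = NA_real_,
                dice_per_cell = numeric(0)))
  gt_sz <- stats::setNames(tabulate(gt[gt > 0L], max(gt_ids)), NULL)
  pr_sz <- if (length(pr_ids) > 0L)
    tabulate(pred[pred > 0L], max(pr_ids)) else integer(0)

  # joint histogram of (gt, pred) over overlapping pixels
  both <- gt > 0L & pred > 0L
  links <- list()
  if (any(both)) {
    key <- paste(gt[both], pred[both])
    tab <- table(key)
    for (k in seq_along(tab)) {
      ids <- as.integer(strsplit(names(tab)[k], " ")[[1]])
      gi <- ids[1]; pi <- ids[2]; inter <- as.integer(tab[[k]])
      un <- gt_sz[gi] + pr_sz[pi] - inter
      iou <- inter / un
      cov <- inter / min(gt_sz[gi], pr_sz[pi])
      if (iou >= iou_min || cov >= 0.5)
        links[[length(links) + 1L]] <-
          c(gt = gi, pred = pi, inter = inter, iou = iou)
    }
  }
  gl <- vapply(links, `[[`, numeric(1), "gt")
  pl <- vapply(links, `[[`, numeric(1), "pred")

  TP <- 0L; over <- 0L; under <- 0L; FN <- 0L
  dpc <- numeric(0)
  for (gi in gt_ids) {
    my <- which(gl == gi)
    if (length(my) == 0L) { FN <- FN + 1L; next }
    preds <- pl[my]
    # degree of the linked predictions on the gt side
    pred_deg <- vapply(preds, function(p) sum(pl == p), numeric(1))
    lenient <- gi %in% division_labels
    if (length(my) == 1L && pred_deg[1] == 1L) {
      TP <- TP + 1L
      dpc[as.character(gi)] <- dice(gt == gi, pred == preds[1])
    } else if (length(my) >= 2L && all(pred_deg == 1L)) {
      if (lenient && length(my) == 2L) TP <- TP + 1L
      else over <- over + 1L
    } else {
      # at least one shared prediction: merged cells
      if (lenient) TP <- TP + 1L else under <- under + 1L
    }
  }
  list(TP = TP, over_seg = over, under_seg = under, FN = FN,
       n_gt = n_gt, accuracy = 100 * TP / n_gt, dice_per_cell = dpc)
}

#' Multiple object tracking precision
#'
#' Mean Euclidean distance between matched ground-truth objects and
#' hypotheses: `sum of distances / total matched pairs`.
#'
#' @param matches data.frame with at least a `distance` column (one row
#'   per matched pair per frame), e.g. from [match_tracks()].
#' @return MOTP in pixels, or NA when there are no matches.
#' @export
motp <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0L) return(NA_real_)
  sum(matches$distance) / nrow(matches)
}

#' Multiple object tracking accuracy
#'
#' Error ratios relative to the total number of ground-truth objects:
#' `FN_ratio = sum FN_t / sum g_t` (misses), likewise for false
#' positives and identity mismatches, and
#' `MOTA = 100 * (1 - sum(FN_t + FP_t + MM_t) / sum g_t)` so that higher
#' is better, matching the reported percentage semantics.
#'
#' @param fn_t,fp_t,mm_t,g_t per-frame error and object counts.
#' @return list with `fn_ratio`, `fp_ratio`, `mm_ratio` (fractions) and
#'   `mota` (%).
#' @export
mota <- function(fn_t, fp_t, mm_t, g_t) {
  G <- sum(g_t)
  if (G <= 0) stop("mota: no ground-truth objects")
  fn <- sum(fn_t) / G; fp <- sum(fp_t) / G; mm <- sum(mm_t) / G
  list(fn_ratio = fn, fp_ratio = fp, mm_ratio = mm,
       mota = 100 * (1 - (fn + fp + mm)))
}

#' Match predicted tracks against ground truth
#'
#' Per-frame correspondence between ground-truth objects and tracker
#' hypotheses: matches persisting from the previous frame are kept while
#' still within `dist_max`; remaining objects are matched greedily by
#' nearest centroid. A mismatch (MM) is counted for a ground-truth track
#' whose matched hypothesis id changes between consecutive frames without
#' a ground-truth division; unmatched objects are misses (FN), unmatched
#' hypotheses false positives (FP).
#'
#' Both inputs are track tables: data.frames with columns `frame`, `id`,
#' `x`, `y` (pixel centroids) and, for the ground truth, `parent`.
#'
#' @param pred_tab predicted track table.
#' @param gt_tab ground-truth track table.
#' @param dist_max gating distance in pixels.
#' @return list with `matches` (frame, gt, hyp, distance), `per_frame`
#'   (frame, FN, FP, MM, g) and totals.
#' @export
match_tracks <- function(pred_tab, gt_tab, dist_max = 5) {
  frames <- sort(unique(gt_tab$frame))
  prev_map <- integer(0)     # gt id -> hyp id at previous frame
  matches <- list(); per_frame <- list()
  for (t in frames) {
    gtt <- gt_tab[gt_tab$frame == t, , drop = FALSE]
    prt <- pred_tab[pred_tab$frame == t, , drop = FALSE]
    map <- stats::setNames(integer(0), character(0))
    used <- integer(0)
    # keep persisting correspondences still within the gate
    for (gi in gtt$id) {
      k <- as.character(gi)
      if (!k %in% names(prev_map)) next
      h <- prev_map[[k]]
      if (!(h %in% prt$id)) next
      grow <- gtt[gtt$id == gi, ]; prow <- prt[prt$id == h, ]
      d <- sqrt((grow$x - prow$x)^2 + (grow$y - prow$y)^2)
      if (d <= dist_max) {
        map[[k]] <- h; used <- c(used, h)
        matches[[length(matches) + 1L]] <-
          data.frame(frame = t, gt = gi, hyp = h, distance = d)
      }
    }
    # greedy nearest-centroid for the rest
    free_g <- setdiff(gtt$id, as.integer(names(map)))
    free_h <- setdiff(prt$id, used)
    if (length(free_g) > 0L && length(free_h) > 0L) {
      gm <- gtt[match(free_g, gtt$id), , drop = FALSE]
      pm <- prt[match(free_h, prt$id), , drop = FALSE]
      dmat <- outer(seq_along(free_g), seq_along(free_h),
                    function(i, j) sqrt((gm$x[i] - pm$x[j])^2 +
                                        (gm$y[i] - pm$y[j])^2))
      repeat {
        if (all(!is.finite(dmat)) || min(dmat) > dist_max) break
        w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        gi <- free_g[w[1]]; h <- free_h[w[2]]
        map[[as.character(gi)]] <- h; used <- c(used, h)
        matches[[length(matches) + 1L]] <-
          data.frame(frame = t, gt = gi, hyp = h,
                     distance = dmat[w[1], w[2]])
        dmat[w[1], ] <- Inf; dmat[, w[2]] <- Inf
      }
    }
    # mismatches: identity changed without a gt division
    mm <- 0L
    for (k in names(map)) {
      if (k %in% names(prev_map) && prev_map[[k]] != map[[k]]) mm <- mm + 1L
    }
    fn <- nrow(gtt) - length(map)
    fp <- nrow(prt) - length(unique(used))
    per_frame[[length(per_frame) + 1L]] <-
      data.frame(frame = t, FN = fn, FP = fp, MM = mm, g = nrow(gtt))
    prev_map <- map
  }
  matches <- if (length(matches) > 0L) do.call(rbind, matches) else
    data.frame(frame = integer(0), gt = integer(0), hyp = integer(0),
               distance = numeric(0))
  per_frame <- do.call(rbind, per_frame)
  list(matches = matches, per_frame = per_frame,
       totals = colSums(per_frame[, c("FN", "FP", "MM", "g")]))
}

#' Full tracking evaluation report
#'
#' Convenience wrapper: matches tracks, computes MOTP/MOTA, and — when
#' label masks are supplied — per-frame segmentation categories and mean
#' Dice.
#'
#' @param pred_tab,gt_tab track tables (see [match_tracks()]).
#' @param pred_labels,gt_labels optional per-frame label mask lists.
#' @param division_labels_by_frame optional list (indexed by frame) of gt
#'   labels under the division leniency rule.
#' @param dist_max,iou_min matching thresholds.
#' @return list with `motp`, `mota` (list), `seg` (aggregated counts and
#'   accuracy) and `mean_dice`, plus the thresholds used.
#' @export
evaluate_tracking <- function(pred_tab, gt_tab, pred_labels = NULL,
                              gt_labels = NULL,
                              division_labels_by_frame = NULL,
                              dist_max = 5, iou_min = 0.5) {
  mt <- match_tracks(pred_tab, gt_tab, dist_max)
  ma <- mota(mt$per_frame$FN, mt$per_frame$FP, mt$per_frame$MM,
             mt$per_frame$g)
  out <- list(motp = motp(mt$matches), mota = ma, match = mt,
              thresholds = list(dist_max = dist_max, iou_min = iou_min))
  if (!is.null(pred_labels) && !is.null(gt_labels)) {
    tot <- c(TP = 0L, over_seg = 0L, under_seg = 0L, FN = 0L, n_gt = 0L)
    dsum <- 0; dn <- 0L
    for (t in seq_along(gt_labels)) {
      dl <- if (!is.null(division_labels_by_frame) &&
                t <= length(division_labels_by_frame))
        division_labels_by_frame[[t]] else integer(0)
      cl <- classify_segmentation(pred_labels[[t]], gt_labels[[t]],
                                  iou_min, division_labels = dl)
      for (nm in names(tot)) tot[nm] <- tot[nm] + cl[[nm]]
      dsum <- dsum + sum(cl$dice_per_cell)
      dn <- dn + length(cl$dice_per_cell)
    }
    out$seg <- as.list(tot)
    out$seg$accuracy <- 100 * tot[["TP"]] / max(tot[["n_gt"]], 1L)
    out$mean_dice <- if (dn > 0L) dsum / dn else NA_real_
  }
  out
}
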