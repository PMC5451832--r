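# Tracking: windows, propagation, septum detection, splits, trajectory
# energies, assignment, full-stack tracking.

rect_region <- function(rows, cols, dims = c(64, 64), label = 1L,
                        frame = 1L, calibration = 0.15) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[rows, cols] <- TRUE
  make_region(m, label, frame, calibration)
}

test_that("window splitting covers the mask with the right count", {
  # 40 x 10 px mask, 10-px windows -> 4 windows
  reg <- rect_region(21:30, 11:50)
  wins <- split_into_windows(reg, w = 1.5, calibration = 0.15)
  expect_length(wins, 4L)
  cover <- matrix(FALSE, 64, 64)
  for (wd in wins)
    cover[wd[["rmin"]]:wd[["rmax"]], wd[["cmin"]]:wd[["cmax"]]] <- TRUE
  expect_true(all(cover[reg$mask]))
  # paper defaults: 0.6 um at 0.15 um/px -> 4 px windows
  wins2 <- split_into_windows(reg, w = 0.6, calibration = 0.15)
  expect_identical(wins2[[1]][["rmax"]] - wins2[[1]][["rmin"]] + 1L, 4L)
  # a window the size of the region -> exactly one window
  reg1 <- rect_region(21:24, 11:14)
  expect_length(split_into_windows(reg1, 0.6, 0.15), 1L)
  expect_error(split_into_windows(reg, w = 0.05, calibration = 0.15),
               "window size")
})

test_that("window classification separates boundary from interior", {
  img <- matrix(100, 64, 64)
  img[, 33:64] <- 220   # vertical edge at column 32/33
  reg <- rect_region(11:50, 11:50)
  wins <- split_into_windows(reg, w = 1.5, calibration = 0.15)
  cls <- classify_windows(wins, smooth_image(img, 1))
  straddles <- vapply(wins, function(wd)
    wd[["cmin"]] <= 35 && wd[["cmax"]] >= 31, logical(1))
  expect_true(all(which(straddles) %in% cls$boundary))
  expect_true(all(setdiff(seq_along(wins), which(straddles)) %in%
                    cls$interior))
  # degenerate: constant image -> everything interior
  cls2 <- classify_windows(wins, matrix(5, 64, 64))
  expect_length(cls2$boundary, 0L)
  expect_identical(cls2$interior, seq_along(wins))
})

test_that("self-propagation reproduces the region", {
  sc <- manual_scene(manual_cells(9.6, 9.6, 0.4, 4.5))
  fr <- render_frame(sc, 1, noise_sd = 0, blur_sd = 1)
  regs <- segment_first_frame(fr$image, seg_config(), drlse_params())
  cand <- propagate_region(regs[[1]], fr$image, track_config(),
                           drlse_params())
  expect_s3_class(cand, "cell_region")
  expect_gte(dice(cand$mask, regs[[1]]$mask), 0.95)
  expect_identical(cand$frame, regs[[1]]$frame + 1L)
})

test_that("propagation follows a 2 px translation", {
  mk <- function(x) {
    sc <- manual_scene(manual_cells(x, 9.6, 0, 4.5))
    render_frame(sc, 1, noise_sd = 0, blur_sd = 1)
  }
  f1 <- mk(9.6); f2 <- mk(9.9)    # +0.3 um = +2 px along x
  regs <- segment_first_frame(f1$image, seg_config(), drlse_params())
  cand <- propagate_region(regs[[1]], f2$image, track_config(),
                           drlse_params())
  gt2 <- make_region(f2$labels == 1, 1L, 2L, 0.15)
  expect_lt(abs(cand$centroid[["x"]] - gt2$centroid[["x"]]), 1)
  expect_lt(abs(cand$centroid[["y"]] - gt2$centroid[["y"]]), 1)
})

test_that("labels never merge: touching cells stay disjoint", {
  sc <- manual_scene(manual_cells(c(8.25, 12.9), c(9.6, 9.6), c(0, 0),
                                  c(4.2, 4.2)))
  fr <- render_frame(sc, 1, noise_sd = 0, blur_sd = 1)
  regs <- segment_first_frame(fr$image, seg_config(), drlse_params())
  expect_length(regs, 2L)
  claimed <- regs[[1]]$mask
  c1 <- propagate_region(regs[[1]], fr$image, track_config(),
                         drlse_params())
  c2 <- propagate_region(regs[[2]], fr$image, track_config(),
                         drlse_params(), claimed = c1$mask)
  expect_false(any(c1$mask & c2$mask))
})

test_that("axis profile: uniform rod has no qualifying extremum, a
          dividing cell has one at mid-axis", {
  sc0 <- manual_scene(manual_cells(9.6, 9.6, 0.3, 6.4, septum = 0))
  f0 <- render_frame(sc0, 1, noise_sd = 0, blur_sd = 1)
  reg0 <- make_region(f0$labels == 1, 1L, 1L, 0.15)
  inv0 <- max(smooth_image(f0$image, 1)) - smooth_image(f0$image, 1)
  p0 <- axis_profile(reg0, inv0)
  expect_null(p0$l_m)
  expect_equal(length(p0$intensities),
               max(3, round(reg0$length_um / 0.15)))

  sc1 <- manual_scene(manual_cells(9.6, 9.6, 0.3, 6.4, septum = 1))
  f1 <- render_frame(sc1, 1, noise_sd = 0, blur_sd = 1)
  reg1 <- make_region(f1$labels == 1, 1L, 1L, 0.15)
  sm1 <- smooth_image(f1$image, 1)
  p1 <- axis_profile(reg1, max(sm1) - sm1)
  expect_false(is.null(p1$l_m))
  mid <- (length(p1$intensities) + 1) / 2
  expect_lte(abs(p1$l_m_index - mid), 2)
})

test_that("septum threshold is mean + tau * sd", {
  x <- c(90, 100, 110)   # mean 100, sd 10
  expect_equal(septum_threshold(x, 1.2), 112)
  expect_equal(septum_threshold(rep(5, 4), 1.2), 5)
  expect_equal(septum_threshold(x, 0), 100)
  expect_error(septum_threshold(numeric(0)), "empty")
})

test_that("division detection applies the threshold to the deepest
          interior minimum", {
  # exhaustive-scan oracle over a small profile
  scan_min <- function(v) {
    n <- length(v)
    cand <- Filter(function(i) v[i] < v[i - 1] && v[i] <= v[i + 1],
                   3:(n - 2))
    if (length(cand) == 0) return(NULL)
    cand[[which.min(v[unlist(cand)])]]
  }
  mk_prof <- function(v) {
    i <- scan_min(v)
    list(positions = seq_along(v) - (length(v) + 1) / 2,
         intensities = v,
         l_m = if (is.null(i)) NULL else v[i],
         l_m_index = if (is.null(i)) NA_integer_ else i)
  }
  v <- c(10, 9, 8, 9, 10)
  expect_identical(scan_min(v), 3L)           # the 8 in the middle
  expect_identical(detect_division(mk_prof(v), 8.5), 3L)
  expect_null(detect_division(mk_prof(v), 7))  # 8 not below 7
  expect_null(detect_division(mk_prof(c(1, 2, 3, 4, 5)), 100))
})

test_that("split_region partitions a capsule at the cut line", {
  sc <- manual_scene(manual_cells(9.6, 9.6, 0.35, 6))
  fr <- render_frame(sc, 1, noise_sd = 0, blur_sd = 0)
  reg <- make_region(fr$labels == 1, 1L, 1L, 0.15)
  n <- max(3L, round(reg$length_um / 0.15))
  prof <- list(positions = seq(-(n - 1) / 2, (n - 1) / 2),
               intensities = rep(0, n))
  mid <- which.min(abs(prof$positions))
  halves <- split_region(reg, mid, prof)
  a1 <- halves[[1]]$area; a2 <- halves[[2]]$area
  expect_identical(a1 + a2, reg$area)          # exact partition
  expect_lt(abs(a1 - a2) / reg$area, 0.05)     # symmetric cut
  # cut at 25% of the axis -> area ratio ~ 1:3
  q <- which.min(abs(prof$positions + n / 4))
  hq <- split_region(reg, q, prof)
  ratio <- min(hq[[1]]$area, hq[[2]]$area) /
    max(hq[[1]]$area, hq[[2]]$area)
  expect_lt(abs(ratio - 1 / 3), 0.1)
  # a cut outside the mask leaves an empty side and is rejected
  far <- list(positions = c(-1000, 1000), intensities = c(0, 0))
  expect_null(split_region(reg, 1L, far))
})

test_that("width splitting only fires above r_w with a real seam", {
  # single 1.0 um cell: unchanged
  sc <- manual_scene(manual_cells(9.6, 9.6, 0, 5, width = 1))
  fr <- render_frame(sc, 1, noise_sd = 0, blur_sd = 1)
  reg <- make_region(fr$labels == 1, 1L, 1L, 0.15)
  sm <- smooth_image(fr$image, 1)
  inv <- max(sm) - sm
  expect_length(split_by_width(reg, 1.2, inv, 50), 1L)
  # two parallel cells fused into one 2 um-wide region
  sc2 <- manual_scene(manual_cells(c(9.6, 9.6), c(9.0, 10.2), c(0, 0),
                                   c(5, 5)))
  f2 <- render_frame(sc2, 1, noise_sd = 0, blur_sd = 1)
  fused <- make_region(f2$labels > 0, 1L, 1L, 0.15)
  expect_gt(fused$width_um, 1.2)
  sm2 <- smooth_image(f2$image, 1)
  inv2 <- max(sm2) - sm2
  bnd <- inv2[boundary_band(fused$mask)]
  out <- split_by_width(fused, 1.2, inv2, septum_threshold(bnd, 1.2))
  expect_length(out, 2L)
  expect_false(any(out[[1]]$mask & out[[2]]$mask))
  # width exactly at r_w: strict inequality keeps it whole
  expect_length(split_by_width(fused, fused$width_um, inv2, 1e6), 1L)
})

test_that("trajectory energies match hand-computed values", {
  st <- function(...) tracking_state(list(...), 10L, calibration = 1)
  tr <- function(id, b, xs, ys = rep(0, length(xs)))
    new_trajectory(id, b, cbind(xs, ys))

  # E_vel
  expect_equal(energy_vel(st(tr(1, 1, c(0, 1, 2, 3)))), 0)
  expect_equal(energy_vel(st(tr(1, 1, c(0, 1, 3)))), 1)
  expect_equal(energy_vel(st(tr(1, 1, 5))), 0)

  # E_exc (r_w in px); two cells at distance r_w for one frame -> 2
  s2 <- st(tr(1, 1, 0), tr(2, 1, 8))
  expect_equal(energy_exc(s2, r_w = 8), 2)
  expect_equal(energy_exc(st(tr(1, 1, c(0, 1))), r_w = 8), 0)
  s3 <- st(tr(1, 1, 0), tr(2, 1, 80))
  expect_equal(energy_exc(s3, r_w = 8), 0.02)
  expect_identical(energy_exc(st(tr(1, 1, 0), tr(2, 1, 0)), 8), Inf)

  # E_reg
  expect_equal(energy_reg(st(tr(1, 1, 5))), 2)
  expect_equal(energy_reg(st(tr(1, 1, rep(0, 5)), tr(2, 1, rep(0, 10)))),
               2.3)
  expect_equal(energy_reg(tracking_state(list(), 5L)), 0)

  # E(X) with default weights (0.02, 0.5, 0.5)
  expect_equal(energy_total(tracking_state(list(), 5L)), 0)
  cfg <- track_config()
  # single trajectory of 3 collinear points, spacing 1 px, r_w = 8 px
  s <- tracking_state(list(tr(1, 1, c(0, 1, 2))), 3L, calibration = 0.15)
  expect_equal(energy_total(s, cfg),
               0.02 * 0 + 0.5 * 0 + 0.5 * (1 + 1 / 3))
  # weights (1, 0, 0) reduce to E_vel
  cfg2 <- track_config(beta = 1, gamma = 0, eta = 0)
  s4 <- tracking_state(list(tr(1, 1, c(0, 1, 3))), 3L)
  expect_equal(energy_total(s4, cfg2), energy_vel(s4))
})

test_that("assignment: unambiguous links are identities; crossing
          tracks resolve by minimum energy", {
  dims <- c(64, 64)
  mkreg <- function(rows, cols, frame)
    rect_region(rows, cols, dims, frame = frame)
  # two straight parallel tracks, frames 1..3
  t1 <- new_trajectory(1, 1, cbind(c(10, 12), c(10, 10)))
  t2 <- new_trajectory(2, 1, cbind(c(10, 12), c(30, 30)))
  r1 <- mkreg(8:12, 12:16, 2); r2 <- mkreg(28:32, 12:16, 2)
  t1$regions[["2"]] <- r1; t2$regions[["2"]] <- r2
  st <- tracking_state(list(t1, t2), 2L)

  # candidates at frame 3 overlapping *both* previous masks (ambiguous)
  ca <- mkreg(8:32, 13:17, 3)   # tall region spanning both rows
  cb <- mkreg(8:32, 13:17, 3)
  ca$centroid <- c(x = 14, y = 10)   # continues track 1
  cb$centroid <- c(x = 14, y = 30)   # continues track 2
  items <- list(list(region = ca, src = NA_integer_),
                list(region = cb, src = NA_integer_))
  out <- assign_optimal(st, items, 3L, track_config())
  p1 <- out$trajectories[["1"]]$positions
  p2 <- out$trajectories[["2"]]$positions
  expect_equal(unname(p1[3, ]), c(14, 10))   # kept, not swapped
  expect_equal(unname(p2[3, ]), c(14, 30))
  # brute force over both assignments agrees
  e_kept <- {
    a <- t1; b <- t2
    a$positions <- rbind(a$positions, c(14, 10)); a$d <- 3L
    b$positions <- rbind(b$positions, c(14, 30)); b$d <- 3L
    energy_total(tracking_state(list(a, b), 3L), track_config())
  }
  e_swap <- {
    a <- t1; b <- t2
    a$positions <- rbind(a$positions, c(14, 30)); a$d <- 3L
    b$positions <- rbind(b$positions, c(14, 10)); b$d <- 3L
    energy_total(tracking_state(list(a, b), 3L), track_config())
  }
  expect_lt(e_kept, e_swap)
})

test_that("assignment handles divisions and keeps uniqueness", {
  t1 <- new_trajectory(1, 1, cbind(c(10, 11), c(10, 10)))
  t1$regions[["2"]] <- rect_region(8:12, 8:12, frame = 2)
  st <- tracking_state(list(t1), 2L)
  d1 <- rect_region(6:9, 10:14, frame = 3)
  d2 <- rect_region(12:15, 10:14, frame = 3)
  items <- list(list(regions = list(d1, d2), src = 1L, division = TRUE))
  out <- assign_optimal(st, items, 3L, track_config())
  expect_length(out$trajectories, 3L)
  mother <- out$trajectories[["1"]]
  expect_identical(mother$d, 2L)
  expect_length(mother$children, 2L)
  kids <- out$trajectories[as.character(mother$children)]
  for (k in kids) {
    expect_identical(k$b, 3L)
    expect_identical(k$parent, 1L)
  }
  # each frame-3 region belongs to exactly one trajectory
  regs <- attr(out, "frame_regions")
  expect_identical(sort(vapply(regs, `[[`, integer(1), "label")),
                   sort(unname(mother$children)))
})

test_that("track_stack: one quiet cell gives one full-length
          trajectory", {
  sc <- simulate_colony(10, seed = 31, n_init = 1, growth_rate = 0,
                        division_length = Inf, image_size = c(96, 96))
  rend <- render_scene(sc)
  res <- track_stack(frame_stack(rend$images, 0.15))
  expect_identical(nrow(res$lineage), 1L)
  expect_identical(res$lineage$b, 1L)
  expect_identical(res$lineage$d, 10L)
  expect_identical(sum(res$events$type == "division"), 0L)
})

test_that("track_stack recovers a scripted division and entry", {
  sc <- simulate_colony(14, seed = 5, n_init = 1, growth_rate = 0.07,
                        init_length = 4.5, image_size = c(128, 128))
  rend <- render_scene(sc)
  res <- track_stack(frame_stack(rend$images, 0.15))
  gt_mother <- sc$lineage[sc$lineage$id %in% sc$lineage$parent, ]
  expect_identical(nrow(gt_mother), 1L)
  expect_identical(nrow(res$lineage), 3L)
  mother <- res$lineage[res$lineage$id %in% res$lineage$parent, ]
  kids <- res$lineage[!is.na(res$lineage$parent), ]
  expect_identical(nrow(kids), 2L)
  expect_true(all(kids$b == mother$d + 1L))
  expect_lte(abs(mother$d - gt_mother$d), 2)

  ent <- data.frame(frame = 5, x = 4, y = 14, angle = 0.2, length = 4)
  sc2 <- simulate_colony(10, seed = 3, n_init = 1,
                         division_length = Inf, entries = ent,
                         image_size = c(128, 128))
  rend2 <- render_scene(sc2)
  res2 <- track_stack(frame_stack(rend2$images, 0.15))
  expect_identical(nrow(res2$lineage), 2L)
  expect_identical(sort(res2$lineage$b), c(1L, 5L))
})

test_that("uniqueness and non-merge hold over a tracked stack, and a
          clean well-separated stack has no mismatches", {
  ev <- benchmark_eval()
  res <- ev$result
  for (t in seq_along(res$regions)) {
    labs <- vapply(res$regions[[t]], `[[`, integer(1), "label")
    expect_false(anyDuplicated(labs) > 0)
    regs <- res$regions[[t]]
    if (length(regs) >= 2)
      for (i in seq_along(regs)) for (j in seq_along(regs))
        if (i < j) expect_false(any(regs[[i]]$mask & regs[[j]]$mask))
  }
  # genealogy consistency
  lin <- res$lineage
  for (i in which(!is.na(lin$parent))) {
    p <- lin[lin$id == lin$parent[i], ]
    expect_identical(lin$b[i], p$d + 1L)
  }
  expect_equal(sum(ev$eval$match$per_frame$MM), 0)
})
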