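# Evaluation metrics: Dice, segmentation categories, MOTP, MOTA, track
# matching.

lab_from <- function(dims, ...) {
  m <- matrix(0L, dims[1], dims[2])
  spots <- list(...)
  for (k in seq_along(spots)) {
    s <- spots[[k]]
    m[s$rows, s$cols] <- s$id
  }
  m
}

test_that("dice follows its closed form and symmetry", {
  A <- matrix(FALSE, 10, 20); A[2:6, 2:11] <- TRUE     # 50 px
  expect_equal(dice(A, A), 1)
  B <- matrix(FALSE, 10, 20); B[7:10, 15:20] <- TRUE   # disjoint
  expect_equal(dice(A, B), 0)
  # |A| = |B| = 100, overlap 50
  A2 <- matrix(FALSE, 20, 20); A2[1:10, 1:10] <- TRUE
  B2 <- matrix(FALSE, 20, 20); B2[6:15, 1:10] <- TRUE
  expect_equal(dice(A2, B2), 0.5)
  expect_equal(dice(B2, A2), 0.5)
  # both empty -> 1 by convention
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice(A, matrix(FALSE, 5, 5)), "shape")
  # monotone under growing overlap
  C1 <- matrix(FALSE, 20, 20); C1[8:17, 1:10] <- TRUE
  expect_lt(dice(A2, C1), dice(A2, B2))
})

test_that("perfect prediction classifies as all TP", {
  gt <- lab_from(c(30, 30), list(id = 1, rows = 2:8, cols = 2:20),
                 list(id = 2, rows = 15:21, cols = 5:25))
  cl <- classify_segmentation(gt, gt)
  expect_identical(cl$TP, 2L)
  expect_identical(cl$over_seg + cl$under_seg + cl$FN, 0L)
  expect_equal(cl$accuracy, 100)
  expect_true(all(cl$dice_per_cell == 1))
})

test_that("a split cell counts as over-segmentation", {
  gt <- lab_from(c(20, 40), list(id = 1, rows = 5:10, cols = 2:33))
  pred <- lab_from(c(20, 40), list(id = 1, rows = 5:10, cols = 2:17),
                   list(id = 2, rows = 5:10, cols = 18:33))
  cl <- classify_segmentation(pred, gt)
  expect_identical(cl$over_seg, 1L)
  expect_identical(cl$TP, 0L)
  # with the division leniency rule the same case is a TP
  cl2 <- classify_segmentation(pred, gt, division_labels = 1L)
  expect_identical(cl2$TP, 1L)
  expect_identical(cl2$over_seg, 0L)
})

test_that("hand-computed 3-cell toy case: merged pair", {
  gt <- lab_from(c(40, 40),
                 list(id = 1, rows = 2:7, cols = 2:21),
                 list(id = 2, rows = 15:20, cols = 2:21),
                 list(id = 3, rows = 25:30, cols = 2:21))
  # cell 1 matched; cells 2 and 3 merged into one object
  pred <- lab_from(c(40, 40),
                   list(id = 7, rows = 2:7, cols = 2:21),
                   list(id = 8, rows = 15:30, cols = 2:21))
  cl <- classify_segmentation(pred, gt)
  expect_identical(cl$TP, 1L)
  expect_identical(cl$under_seg, 2L)
  expect_identical(cl$FN, 0L)
  expect_equal(cl$accuracy, 100 / 3, tolerance = 1e-9)
  # conservation: TP + over + under + FN = total gt cells
  expect_identical(cl$TP + cl$over_seg + cl$under_seg + cl$FN, cl$n_gt)
})

test_that("undetected cells are false negatives and conservation holds
          on random label images", {
  gt <- lab_from(c(20, 20), list(id = 1, rows = 3:8, cols = 3:14))
  pred <- matrix(0L, 20, 20)
  cl <- classify_segmentation(pred, gt)
  expect_identical(cl$FN, 1L)
  set.seed(7)
  for (rep in 1:5) {
    dims <- c(48, 48)
    gt <- matrix(0L, dims[1], dims[2])
    for (id in 1:4) {
      r0 <- sample(1:40, 1); c0 <- sample(1:40, 1)
      gt[r0:(r0 + 6), c0:(c0 + 6)][gt[r0:(r0 + 6), c0:(c0 + 6)] == 0] <- id
    }
    pr <- gt
    pr[sample(length(pr), 300)] <- 0L   # random erosion of the prediction
    cl <- classify_segmentation(pr, gt)
    expect_identical(cl$TP + cl$over_seg + cl$under_seg + cl$FN, cl$n_gt)
  }
})

test_that("motp is the mean matched distance", {
  expect_equal(motp(data.frame(distance = 3)), 3)
  expect_equal(motp(data.frame(distance = c(2, 4))), 3)
  expect_true(is.na(motp(data.frame(distance = numeric(0)))))
})

test_that("mota aggregates error ratios with the complement
          convention", {
  expect_equal(mota(0, 0, 0, c(5, 5))$mota, 100)
  r <- mota(c(3, 2), c(2, 1), c(1, 1), c(60, 40))
  expect_equal(r$fn_ratio, 0.05)
  expect_equal(r$fp_ratio, 0.03)
  expect_equal(r$mm_ratio, 0.02)
  expect_equal(r$mota, 90)
  # everything missed
  expect_equal(mota(c(10, 10), 0, 0, c(10, 10))$mota, 0)
  expect_error(mota(0, 0, 0, 0), "ground-truth")
  # monotone: any extra error lowers MOTA
  expect_lt(mota(1, 0, 0, 100)$mota, mota(0, 0, 0, 100)$mota)
  expect_lt(mota(0, 1, 0, 100)$mota, mota(0, 0, 0, 100)$mota)
  expect_lt(mota(0, 0, 1, 100)$mota, mota(0, 0, 0, 100)$mota)
})

test_that("track matching: perfect tracks give zero errors", {
  gt <- data.frame(frame = rep(1:5, each = 2), id = rep(1:2, 5),
                   parent = NA, x = rep(c(10, 30), 5) + rep(0:4, each = 2),
                   y = 10)
  mt <- match_tracks(gt, gt)
  expect_equal(unname(mt$totals), c(0, 0, 0, 10))
  expect_equal(motp(mt$matches), 0)
})

test_that("an identity swap costs two mismatches at that frame", {
  gt <- data.frame(frame = rep(1:4, each = 2), id = rep(1:2, 4),
                   parent = NA,
                   x = rep(c(10, 30), 4), y = 10)
  pred <- gt
  # swap predicted ids from frame 3 on
  sw <- pred$frame >= 3
  pred$id[sw] <- ifelse(pred$id[sw] == 1, 2, 1)
  mt <- match_tracks(pred, gt)
  expect_equal(mt$per_frame$MM, c(0, 0, 2, 0))
})

test_that("a one-frame dropout is a miss in that frame only", {
  gt <- data.frame(frame = rep(1:4, each = 2), id = rep(1:2, 4),
                   parent = NA, x = rep(c(10, 30), 4), y = 10)
  pred <- gt[!(gt$frame == 3 & gt$id == 2), ]
  mt <- match_tracks(pred, gt)
  expect_equal(mt$per_frame$FN, c(0, 0, 1, 0))
  expect_equal(sum(mt$per_frame$FP), 0)
  expect_equal(sum(mt$per_frame$MM), 0)
})

test_that("gating distance separates matches from false positives", {
  gt <- data.frame(frame = 1, id = 1, parent = NA, x = 10, y = 10)
  pred <- data.frame(frame = 1, id = 9, x = 30, y = 30)
  mt <- match_tracks(pred, gt, dist_max = 5)
  expect_equal(unname(mt$totals), c(1, 1, 0, 1))
})
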