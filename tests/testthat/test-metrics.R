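test_that("dice handles identity, disjoint and partial overlap", {
  A <- as_mask(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(dice(A, A), 100)
  B <- as_mask(matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(dice(A, B), 0)
  # |A| = |B| = 4, |A n B| = 2 -> 50
  A4 <- as_mask(matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3))
  B4 <- as_mask(matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0), 3, 3))
  expect_equal(dice(A4, B4), 50)
  expect_equal(dice(A4, B4), dice(B4, A4))
})

test_that("both-empty masks score 100 with a warning flag", {
  E <- as_mask(matrix(0L, 3, 3))
  expect_warning(d <- dice(E, E), "empty")
  expect_equal(as.numeric(d), 100)
  expect_true(attr(d, "both_empty"))
  expect_warning(i <- miou(E, E), "empty")
  expect_equal(as.numeric(i), 100)
})

test_that("iou follows the printed single-class formula", {
  # |A n B| = 2, |A u B| = 6 -> 33.33..
  A <- as_mask(matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3))
  B <- as_mask(matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0), 3, 3))
  expect_equal(miou(A, B), 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(miou(A, A), 100)
  # the optional two-class mean includes background IoU
  expect_gt(miou(A, B, mean_classes = TRUE), miou(A, B))
})

test_that("dice and iou satisfy Dice = 2 IoU / (1 + IoU) on random pairs", {
  set.seed(31)
  for (i in 1:40) {
    A <- as_mask(rand_mask(12, 12, runif(1, 0.2, 0.8)))
    B <- as_mask(rand_mask(12, 12, runif(1, 0.2, 0.8)))
    if (sum(A) + sum(B) == 0L) next
    iou <- miou(A, B) / 100
    expect_equal(dice(A, B) / 100, 2 * iou / (1 + iou), tolerance = 1e-9)
  }
})

test_that("hausdorff distance matches hand geometry and is symmetric", {
  A <- as_mask(matrix(0L, 6, 6)); A[1, 1] <- 1L
  B <- as_mask(matrix(0L, 6, 6)); B[4, 5] <- 1L # offset (3, 4) -> 5 mm at 1 mm/px
  expect_equal(hausdorff_mm(A, B, c(1, 1)), 5)
  expect_equal(hausdorff_mm(B, A, c(1, 1)), 5)
  expect_equal(hausdorff_mm(A, A, c(1, 1)), 0)
  # anisotropic pixels scale each axis separately
  expect_equal(hausdorff_mm(A, B, c(2, 0.5)), sqrt((3 * 2)^2 + (4 * 0.5)^2))
  expect_error(hausdorff_mm(A, as_mask(matrix(0L, 6, 6))), "empty")
})

test_that("distance-transform hausdorff equals brute force on random masks", {
  set.seed(32)
  for (i in 1:25) {
    A <- rand_mask(14, 14, 0.25)
    B <- rand_mask(14, 14, 0.25)
    if (!any(A == 1L) || !any(B == 1L)) next
    ps <- c(runif(1, 0.1, 2), runif(1, 0.1, 2))
    expect_equal(hausdorff_mm(as_mask(A), as_mask(B), ps),
                 brute_hausdorff(A, B, ps), tolerance = 1e-9)
  }
})

test_that("apde is the mean pixel-size-weighted absolute distance error", {
  expect_equal(apde(data.frame(d_manual_px = 100, d_pred_px = 90, px_mm = 0.2)), 2.0)
  expect_equal(apde(data.frame(d_manual_px = c(10, 20), d_pred_px = c(20, 40),
                               px_mm = c(0.2, 0.2))), 3.0) # (2 + 4) / 2
  expect_equal(apde(data.frame(d_manual_px = 1:5, d_pred_px = 1:5, px_mm = 0.3)), 0)
  expect_error(apde(data.frame()), "non-empty")
  # scale equivariance: doubling every pixel size doubles the error
  set.seed(33)
  rec <- data.frame(d_manual_px = sample(0:80, 20), d_pred_px = sample(0:80, 20),
                    px_mm = runif(20, 0.1, 0.5))
  rec2 <- transform(rec, px_mm = 2 * px_mm)
  expect_equal(apde(rec2), 2 * apde(rec), tolerance = 1e-12)
})

test_that("pearson correlation matches hand-computed and degenerate cases error", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "degenerate")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("bland-altman limits follow mean +/- 1.96 sd of the differences", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(unlist(ba0), c(mean_diff = 0, loa_low = 0, loa_high = 0))
  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$mean_diff, 2)
  expect_equal(ba2$loa_low, 2)
  expect_equal(ba2$loa_high, 2)
  # differences (-1, 0, 1): sd = 1 -> limits at +/- 1.96
  ba <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, -1.96, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96, tolerance = 1e-12)
})

test_that("evaluate_masks assembles per-image records and aggregates", {
  set.seed(34)
  gt <- lapply(1:5, function(i) generate_phantom(phantom_spec(gap_mm = 5 * i, seed = i))$mask)
  pred <- gt
  pred[[2]] <- as_mask(matrix(0L, 128, 128), attr(gt[[2]], "pixel_size_mm")) # one failure
  ev <- suppressWarnings(evaluate_masks(pred, gt))
  expect_identical(nrow(ev$per_image), 5L)
  expect_equal(ev$per_image$dice_pct[1], 100)
  expect_equal(ev$per_image$dice_pct[2], 0)
  expect_true(is.na(ev$per_image$hd_mm[2])) # HD undefined for the empty prediction
  expect_equal(ev$apde_mm, mean(ev$per_image$abs_dist_err_mm))
  expect_true(ev$bland_altman$loa_low <= ev$bland_altman$mean_diff)
  expect_true(ev$bland_altman$mean_diff <= ev$bland_altman$loa_high)
})
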