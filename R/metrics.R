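# Segmentation evaluation metrics (Dice, IoU, Hausdorff distance, average
# physical distance error) and method-agreement statistics (Pearson,
# Bland-Altman).

overlap_counts <- function(A, B) {
  check_binary(A, "A"); check_binary(B, "B")
  if (!identical(dim(A), dim(B))) stopf("masks must share a grid")
  list(a = sum(A != 0), b = sum(B != 0), i = sum(A != 0 & B != 0),
       u = sum(A != 0 | B != 0))
}

#' Dice overlap coefficient (percent)
#'
#' `Dice = 2|A n B| / (|A| + |B|)`, returned in percent. Two empty masks
#' agree perfectly by convention: the result is 100 with attribute
#' `both_empty = TRUE` (and a warning), since 0/0 is otherwise undefined.
#'
#' @param A,B binary masks on one grid (prediction and ground truth; the
#'   measure is symmetric).
#' @return Dice score in `[0, 100]`.
#' @export
dice <- function(A, B) {
  n <- overlap_counts(A, B)
  if (n$a + n$b == 0L) {
    warning("both masks empty; Dice defined as 100", call. = FALSE)
    return(structure(100, both_empty = TRUE))
  }
  200 * n$i / (n$a + n$b)
}

#' Foreground intersection-over-union (percent)
#'
#' `IoU = |A n B| / |A u B|` in percent for the muscle foreground class.
#' With `mean_classes = TRUE` the mean of foreground and background IoU is
#' returned instead (the two-class reading of "mean IoU").
#'
#' @inheritParams dice
#' @param mean_classes average foreground and background IoU.
#' @return IoU in `[0, 100]`.
#' @export
miou <- function(A, B, mean_classes = FALSE) {
  n <- overlap_counts(A, B)
  if (n$u == 0L) {
    warning("both masks empty; IoU defined as 100", call. = FALSE)
    return(structure(100, both_empty = TRUE))
  }
  fg <- 100 * n$i / n$u
  if (!mean_classes) return(fg)
  tot <- length(A)
  bg_i <- tot - n$u
  bg_u <- tot - n$i
  (fg + 100 * bg_i / bg_u) / 2
}

#' Hausdorff distance between two masks, in mm
#'
#' `HD = max(h(A,B), h(B,A))` where `h(A,B)` is the largest distance from a
#' foreground pixel of A to its nearest foreground pixel of B. Distances are
#' Euclidean in physical units, using the per-axis pixel sizes, and are
#' computed over the full foreground point sets via an exact distance
#' transform (equivalent to the brute-force max-min definition).
#'
#' @inheritParams dice
#' @param pixel_size_mm per-axis pixel size (row, col) in mm; defaults to
#'   the masks' attribute.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_mm <- function(A, B, pixel_size_mm = NULL) {
  check_binary(A, "A"); check_binary(B, "B")
  if (!identical(dim(A), dim(B))) stopf("masks must share a grid")
  if (!any(A != 0) || !any(B != 0))
    stopf("Hausdorff distance is undefined for an empty mask")
  ps <- if (is.null(pixel_size_mm)) mask_pixel_size(A) else check_pixel_size(pixel_size_mm)
  Ai <- matrix(as.integer(A != 0), nrow(A), ncol(A))
  Bi <- matrix(as.integer(B != 0), nrow(B), ncol(B))
  dB <- cpp_edt_sq(Bi, ps[1], ps[2]) # squared mm distance to nearest B pixel
  dA <- cpp_edt_sq(Ai, ps[1], ps[2])
  hAB <- sqrt(max(dB[Ai == 1L]))
  hBA <- sqrt(max(dA[Bi == 1L]))
  max(hAB, hBA)
}

#' Average physical distance error (APDE), in mm
#'
#' Mean over images of the pixel size times the absolute difference between
#' the manually measured and the automatically computed inter-muscle pixel
#' distances: `APDE = (1/N) sum_i p_i |d_i - dhat_i|`.
#'
#' @param records data.frame with columns `d_manual_px`, `d_pred_px`,
#'   `px_mm` (one row per image).
#' @return APDE in mm.
#' @export
apde <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("records must be a non-empty data.frame")
  need <- c("d_manual_px", "d_pred_px", "px_mm")
  if (!all(need %in% names(records)))
    stopf("records needs columns %s", paste(need, collapse = ", "))
  if (any(records$px_mm <= 0)) stopf("px_mm must be positive")
  mean(records$px_mm * abs(records$d_manual_px - records$d_pred_px))
}

#' Sample Pearson correlation
#'
#' Thin wrapper over [stats::cor()] with the degenerate cases rejected
#' explicitly (fewer than 3 pairs, or a constant vector).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("degenerate input: constant vector")
  cor(x, y, method = "pearson")
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `y - x` (second method minus first); the 95%
#' limits of agreement are `mean_diff +/- 1.96 * sd` with the sample
#' standard deviation (n-1 denominator).
#'
#' @param x,y paired measurements (e.g. manual and automatic distances, mm).
#' @return list with `mean_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 pairs")
  d <- y - x
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the per-image segmentation metrics and the distance-based
#' agreement statistics for a test set, yielding the per-image records and
#' aggregate mean +/- sd of each metric.
#'
#' @param pred_masks,gt_masks lists of binary masks on one shared grid
#'   (predictions already post-processed).
#' @param pixel_size_mm per-axis pixel size shared by all masks, or a list
#'   of per-image sizes.
#' @return list of class `ra_eval`: `per_image` data.frame (`dice_pct`,
#'   `iou_pct`, `hd_mm`, `d_manual_px`, `d_pred_px`, `px_mm`,
#'   `abs_dist_err_mm`), `aggregate` (mean/sd per metric), `apde_mm`,
#'   `pearson_r`, `bland_altman` (on the physical distances, predicted vs
#'   manual).
#' @export
evaluate_masks <- function(pred_masks, gt_masks, pixel_size_mm = NULL) {
  if (length(pred_masks) != length(gt_masks) || length(pred_masks) == 0L)
    stopf("need equal, non-zero numbers of predicted and ground-truth masks")
  n <- length(pred_masks)
  rec <- data.frame(dice_pct = numeric(n), iou_pct = numeric(n),
                    hd_mm = numeric(n), d_manual_px = integer(n),
                    d_pred_px = integer(n), px_mm = numeric(n),
                    abs_dist_err_mm = numeric(n))
  for (i in seq_len(n)) {
    A <- pred_masks[[i]]; B <- gt_masks[[i]]
    ps <- if (is.null(pixel_size_mm)) mask_pixel_size(B)
          else if (is.list(pixel_size_mm)) check_pixel_size(pixel_size_mm[[i]])
          else check_pixel_size(pixel_size_mm)
    rec$dice_pct[i] <- as.numeric(dice(A, B))
    rec$iou_pct[i] <- as.numeric(miou(A, B))
    rec$hd_mm[i] <- if (any(A != 0) && any(B != 0)) hausdorff_mm(A, B, ps) else NA_real_
    mp <- measure_distance(keep_two_largest(B), px_mm = ps[2])
    ma <- measure_distance(keep_two_largest(A), px_mm = ps[2])
    rec$d_manual_px[i] <- mp$d_px
    rec$d_pred_px[i] <- ma$d_px
    rec$px_mm[i] <- ps[2]
    rec$abs_dist_err_mm[i] <- abs(mp$D_mm - ma$D_mm)
  }
  agg <- sapply(c("dice_pct", "iou_pct", "hd_mm", "abs_dist_err_mm"),
                function(k) mean_sd(rec[[k]]))
  manual_mm <- rec$d_manual_px * rec$px_mm
  pred_mm <- rec$d_pred_px * rec$px_mm
  r <- if (sd(manual_mm) > 0 && sd(pred_mm) > 0 && n >= 3L)
    pearson_r(manual_mm, pred_mm) else NA_real_
  ba <- if (n >= 3L) bland_altman(manual_mm, pred_mm) else NULL
  structure(list(per_image = rec, aggregate = agg, apde_mm = apde(rec),
                 pearson_r = r, bland_altman = ba),
            class = "ra_eval")
}

#' @export
print.ra_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<ra_eval: n = %d images>\n  Dice %.2f +/- %.2f %%  IoU %.2f +/- %.2f %%\n  HD %.2f +/- %.2f mm  APDE %.3f mm  Pearson r %.3f\n",
    nrow(x$per_image), a["mean", "dice_pct"], a["sd", "dice_pct"],
    a["mean", "iou_pct"], a["sd", "iou_pct"],
    a["mean", "hd_mm"], a["sd", "hd_mm"], x$apde_mm,
    if (is.na(x$pearson_r)) NA else x$pearson_r))
  invisible(x)
}
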