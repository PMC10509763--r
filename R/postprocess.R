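# Post-processing of network probability maps: threshold, connected
# components, and the at-most-two-regions rule (each rectus abdominis body
# is one region; anything smaller is segmentation noise).

#' Binarize a probability map
#'
#' The strict rule `p > threshold` is used, so values exactly at the
#' threshold become background.
#'
#' @param prob numeric matrix of per-pixel foreground probabilities in
#'   `[0, 1]` (a `pixel_size_mm` attribute, if present, is propagated).
#' @param threshold scalar in (0, 1); default 0.5.
#' @param pixel_size_mm optional explicit pixel size for the output mask.
#' @return binary mask matrix.
#' @export
binarize <- function(prob, threshold = 0.5, pixel_size_mm = NULL) {
  if (!is.matrix(prob)) stopf("prob must be a matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly between 0 and 1")
  ps <- if (is.null(pixel_size_mm)) mask_pixel_size(prob) else check_pixel_size(pixel_size_mm)
  as_mask(prob > threshold, ps)
}

#' Label connected components of a binary mask
#'
#' Components are returned sorted by decreasing area; equal areas are
#' ordered by smaller leftmost bounding column. Rectangle bounds are 0-based
#' and inclusive.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list of class `ra_regions`: `regions`, a data.frame with columns
#'   `label`, `area`, `row_min`, `row_max`, `col_min`, `col_max`,
#'   `centroid_row`, `centroid_col`; and `labels`, the integer label matrix
#'   (0 = background, labels as in `regions$label`).
#' @export
label_regions <- function(mask, connectivity = 8L) {
  check_binary(mask)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                              as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    regions <- data.frame(label = integer(), area = integer(),
                          row_min = integer(), row_max = integer(),
                          col_min = integer(), col_max = integer(),
                          centroid_row = numeric(), centroid_col = numeric())
    return(structure(list(regions = regions, labels = lab), class = "ra_regions"))
  }
  H <- nrow(mask)
  li <- lab[idx]
  rows <- (idx - 1L) %% H          # 0-based
  cols <- (idx - 1L) %/% H
  regions <- data.frame(
    label = sort(unique(li)),
    area = as.integer(tapply(li, li, length)),
    row_min = as.integer(tapply(rows, li, min)),
    row_max = as.integer(tapply(rows, li, max)),
    col_min = as.integer(tapply(cols, li, min)),
    col_max = as.integer(tapply(cols, li, max)),
    centroid_row = as.numeric(tapply(rows, li, mean)),
    centroid_col = as.numeric(tapply(cols, li, mean)),
    row.names = NULL)
  regions <- regions[order(-regions$area, regions$col_min), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, labels = lab), class = "ra_regions")
}

#' @export
print.ra_regions <- function(x, ...) {
  cat(sprintf("<ra_regions: %d component(s)>\n", nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Keep the two largest connected components
#'
#' Implements the post-processing rule that at most two muscle regions
#' remain: all but the two largest components (area ties broken toward the
#' smaller leftmost bounding column) are removed. Idempotent; the output
#' foreground is always a subset of the input foreground.
#'
#' @inheritParams label_regions
#' @return binary mask with at most two components.
#' @export
keep_two_largest <- function(mask, connectivity = 8L) {
  regs <- label_regions(mask, connectivity)
  if (nrow(regs$regions) <= 2L) return(as_mask(mask, mask_pixel_size(mask)))
  keep <- regs$regions$label[1:2]
  as_mask(matrix(regs$labels %in% keep, nrow(mask), ncol(mask)),
          mask_pixel_size(mask))
}
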