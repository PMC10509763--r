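# Preprocessing: turn a raw exported frame (scan region surrounded by a
# black annotation periphery) into a fixed-size model input while keeping
# the mm-per-pixel bookkeeping exact.

#' Otsu threshold of an 8-bit image
#'
#' Returns the intensity level `t` (0-254) that maximizes the between-class
#' variance when pixels are split into `{<= t}` and `{> t}`. Ties are broken
#' toward the lower level.
#'
#' @param pixels integer matrix/vector of intensities in `[0, 255]`.
#' @return integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.integer(pixels)
  if (any(v < 0L | v > 255L)) stopf("otsu_threshold expects 8-bit intensities")
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) stopf("degenerate input: image has a single intensity level")
  p <- h / sum(h)
  omega <- cumsum(p)           # P(class0) for t = 0..255
  mu <- cumsum(p * (0:255))    # first moment up to t
  mu_t <- mu[256L]
  w0 <- omega[1:255]
  sigma_b <- (mu_t * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L      # first maximum = lowest tying level
}

#' Crop a raw frame to its ultrasound scan region
#'
#' Binarizes at the Otsu threshold, labels foreground components
#' (8-connectivity), keeps the largest-area component and crops the frame to
#' its minimum enclosing axis-aligned rectangle. This removes the black
#' periphery that carries burned-in device/acquisition text. Pixel sizes are
#' unchanged by cropping.
#'
#' @param frame an [new_frame()] object.
#' @return a list of class `ra_crop` with `cropped` (an `ra_frame`) and
#'   `box`, the rectangle `c(row_min, row_max, col_min, col_max)` in 0-based
#'   inclusive raw-frame coordinates.
#' @export
strip_periphery <- function(frame) {
  stopifnot(inherits(frame, "ra_frame"))
  t <- otsu_threshold(frame$pixels)
  fg <- matrix(as.integer(frame$pixels > t), nrow(frame$pixels), ncol(frame$pixels))
  if (!any(fg == 1L)) stopf("degenerate input: empty foreground after thresholding")
  regs <- label_regions(as_mask(fg, frame$pixel_size_mm), connectivity = 8L)
  top <- regs$regions[1L, ] # largest area, ties toward smaller col_min
  box <- c(row_min = top$row_min, row_max = top$row_max,
           col_min = top$col_min, col_max = top$col_max)
  cropped <- new_frame(
    frame$pixels[(box[1] + 1L):(box[2] + 1L), (box[3] + 1L):(box[4] + 1L), drop = FALSE],
    frame$pixel_size_mm, source_id = frame$source_id)
  structure(list(cropped = cropped, box = box), class = "ra_crop")
}

#' Resize a frame to the square model grid
#'
#' Bilinear interpolation (half-pixel-center convention); the per-axis pixel
#' size is rescaled by `old_extent / target` so the physical extent of the
#' image is preserved. Resizing a non-square crop to a square grid is
#' anisotropic; the column-axis (lateral) pixel size is the one later used
#' to convert pixel gaps to mm.
#'
#' @param frame an [new_frame()] object.
#' @param target output side length in pixels (default 512).
#' @return an `ra_frame` of size `target x target`.
#' @export
resize_to_model <- function(frame, target = 512L) {
  stopifnot(inherits(frame, "ra_frame"))
  target <- as.integer(target)
  if (is.na(target) || target < 8L) stopf("target size must be an integer >= 8")
  d <- dim(frame$pixels)
  y <- cpp_resize_bilinear(frame$pixels + 0.0, target, target)
  new_frame(clamp255(round(y)),
            frame$pixel_size_mm * d / target,
            source_id = frame$source_id)
}

#' Resize a binary mask with the transform of [resize_to_model()]
#'
#' Nearest-neighbour resampling so the mask stays strictly binary; pixel
#' sizes are rescaled exactly as for the image so image and mask remain on
#' one shared grid.
#'
#' @param mask binary matrix with a `pixel_size_mm` attribute.
#' @param target output side length in pixels.
#' @return resized binary mask.
#' @export
resize_mask <- function(mask, target = 512L) {
  check_binary(mask)
  target <- as.integer(target)
  if (is.na(target) || target < 8L) stopf("target size must be an integer >= 8")
  ps <- mask_pixel_size(mask)
  y <- cpp_resize_nearest(mask + 0.0, target, target)
  as_mask(y, ps * dim(mask) / target)
}
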