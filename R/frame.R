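#' Construct a calibrated ultrasound frame
#'
#' A frame is an 8-bit grayscale image together with its physical pixel size.
#' Pixel sizes are tracked per axis (row, column) in mm/pixel so that
#' anisotropic resampling keeps physical distances measurable; the lateral
#' (column) size is the one that converts an inter-muscle pixel gap to mm.
#'
#' @param pixels integer matrix of intensities in `[0, 255]` (rows = image
#'   rows, columns = image columns).
#' @param pixel_size_mm positive numeric of length 1 (isotropic) or 2
#'   (row-axis, column-axis), in mm/pixel.
#' @param source_id free-form identifier carried through the pipeline.
#' @return an object of class `ra_frame` with fields `pixels`,
#'   `pixel_size_mm` (length 2) and `source_id`.
#' @export
new_frame <- function(pixels, pixel_size_mm, source_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stopf("pixels must be a non-empty matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stopf("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
         pixel_size_mm = check_pixel_size(pixel_size_mm),
         source_id = as.character(source_id)),
    class = "ra_frame")
}

#' @export
print.ra_frame <- function(x, ...) {
  cat(sprintf("<ra_frame %s: %d x %d px, %.4g x %.4g mm/px>\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_mm[1], x$pixel_size_mm[2]))
  invisible(x)
}

#' @export
dim.ra_frame <- function(x) dim(x$pixels)

#' Load an ultrasound frame from PNG or DICOM
#'
#' PNG images are converted to 8-bit luminance (Rec. 601 weights for RGB
#' input). For DICOM input the file's `PixelSpacing` calibration, when
#' present, takes precedence over the `pixel_size_mm` argument;
#' `MONOCHROME1` photometric interpretation is inverted so that higher
#' values are always brighter.
#'
#' @param path path to a PNG file or an uncompressed little-endian DICOM
#'   file.
#' @param pixel_size_mm fallback calibration in mm/pixel (length 1 or 2);
#'   required when the file carries none.
#' @return an [new_frame()] object.
#' @export
load_frame <- function(path, pixel_size_mm = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stopf("cannot read frame: file not found: %s", path)
  if (is_dicom_file(path)) {
    dcm <- read_dicom_minimal(path)
    ps <- if (!is.null(dcm$pixel_spacing_mm)) dcm$pixel_spacing_mm else pixel_size_mm
    if (is.null(ps))
      stopf("no pixel-size calibration: file has no PixelSpacing and no pixel_size_mm given")
    return(new_frame(dcm$pixels, ps, source_id = basename(path)))
  }
  img <- tryCatch(png::readPNG(path), error = function(e)
    stopf("cannot read frame %s: %s", path, conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  if (is.null(pixel_size_mm))
    stopf("no pixel-size calibration: PNG carries none, pixel_size_mm is required")
  new_frame(round(img * 255), pixel_size_mm, source_id = basename(path))
}

#' Write a frame (or mask) as 8-bit grayscale PNG
#'
#' @param x an `ra_frame`, or a matrix of intensities in `[0, 255]`
#'   (binary masks are scaled to 0/255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(x, path) {
  m <- if (inherits(x, "ra_frame")) x$pixels else x
  if (all(m %in% c(0L, 1L))) m <- m * 255L
  png::writePNG(m / 255, target = path)
  invisible(path)
}
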