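# internal helpers

clamp255 <- function(x) pmin(pmax(x, 0), 255)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# per-axis pixel size: accept scalar (isotropic) or length-2 (row, col)
check_pixel_size <- function(pixel_size_mm) {
  if (is.null(pixel_size_mm) || !is.numeric(pixel_size_mm) ||
      !length(pixel_size_mm) %in% c(1L, 2L) || any(pixel_size_mm <= 0) ||
      any(!is.finite(pixel_size_mm)))
    stopf("pixel_size_mm must be one or two positive finite numbers (mm/pixel)")
  if (length(pixel_size_mm) == 1L) pixel_size_mm <- rep(pixel_size_mm, 2L)
  unname(as.numeric(pixel_size_mm))
}

#' Construct a binary mask
#'
#' A mask is an integer 0/1 matrix carrying a `pixel_size_mm` attribute
#' (row-axis, column-axis mm/pixel); any nonzero/`TRUE` input value becomes
#' foreground.
#'
#' @param values matrix (logical, integer or numeric).
#' @param pixel_size_mm positive numeric of length 1 or 2, in mm/pixel.
#' @return integer 0/1 matrix with the `pixel_size_mm` attribute set.
#' @export
as_mask <- function(values, pixel_size_mm = c(1, 1)) {
  if (!is.matrix(values)) stopf("mask must be a matrix")
  m <- matrix(as.integer(values != 0), nrow(values), ncol(values))
  attr(m, "pixel_size_mm") <- check_pixel_size(pixel_size_mm)
  m
}

mask_pixel_size <- function(mask, pixel_size_mm = NULL) {
  if (!is.null(pixel_size_mm)) return(check_pixel_size(pixel_size_mm))
  ps <- attr(mask, "pixel_size_mm")
  if (is.null(ps)) c(1, 1) else check_pixel_size(ps)
}

check_binary <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stopf("%s must be a matrix", what)
  if (!all(mask %in% c(0L, 1L, 0, 1, TRUE, FALSE)))
    stopf("%s must be binary (0/1)", what)
  invisible(mask)
}

# mean +/- sd (sample sd, n-1) used for aggregate reporting
mean_sd <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0)
}
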