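# Tiny writer for explicit-VR little-endian DICOM fixtures (preamble +
# DICM magic + the handful of image-module elements the reader needs).

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
                              (x %/% 65536L) %% 256L, x %/% 16777216L))

dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT", "OF")) {
    c(hdr, as.raw(c(0L, 0L)), u32le(length(value)), value)
  } else {
    c(hdr, u16le(length(value)), value)
  }
}

# pixels: integer matrix (values 0..255 for 8-bit); written row-major
write_test_dicom <- function(path, pixels, spacing = NULL,
                             photometric = "MONOCHROME2", bits = 8L) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  pd_vals <- as.integer(t(pixels)) # row-major
  pd <- if (bits == 8L) as.raw(pd_vals) else
    writeBin(pd_vals, raw(), size = 2L, endian = "little")
  out <- c(raw(128L), charToRaw("DICM"),
           dcm_elem(0x0028L, 0x0004L, "CS", photometric),
           dcm_elem(0x0028L, 0x0010L, "US", u16le(rows)),
           dcm_elem(0x0028L, 0x0011L, "US", u16le(cols)))
  if (!is.null(spacing))
    out <- c(out, dcm_elem(0x0028L, 0x0030L, "DS",
                           paste(format(spacing, trim = TRUE), collapse = "\\")))
  out <- c(out,
           dcm_elem(0x0028L, 0x0100L, "US", u16le(bits)),
           dcm_elem(0x0028L, 0x0101L, "US", u16le(bits)),
           dcm_elem(0x0028L, 0x0103L, "US", u16le(0L)),
           dcm_elem(0x7fe0L, 0x0010L, "OB", pd))
  writeBin(out, path)
  invisible(path)
}
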