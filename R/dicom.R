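# Minimal DICOM reader for single-frame grayscale images.
#
# Scope: uncompressed pixel data, little-endian transfer syntaxes (explicit
# or implicit VR), MONOCHROME1/2, 8- or 16-bit. This covers files exported
# directly from an ultrasound console; encapsulated/compressed transfer
# syntaxes and sequences of undefined length are rejected with an error.

is_dicom_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n)) return(FALSE)
  if (n >= 132L) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", 132L)
    if (identical(hdr[129:132], charToRaw("DICM"))) return(TRUE)
  }
  grepl("\\.(dcm|dicom)$", tolower(path))
}

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
read_u32 <- function(raw, off) {
  read_u16(raw, off) + 65536 * read_u16(raw, off + 2L)
}

explicit_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 0L
  if (length(raw) >= 132L && identical(raw[129:132], charToRaw("DICM")))
    pos <- 132L
  # sniff explicit VR: bytes 5-6 of the first element are two uppercase letters
  vr_bytes <- raw[pos + 5:6]
  explicit <- all(vr_bytes >= as.raw(0x41) & vr_bytes <= as.raw(0x5a))
  tags <- list()
  while (pos + 8L <= length(raw)) {
    grp <- read_u16(raw, pos); el <- read_u16(raw, pos + 2L)
    key <- sprintf("%04x,%04x", grp, el)
    if (explicit && grp != 0xfffe) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% explicit_long_vrs) {
        len <- read_u32(raw, pos + 8L); pos <- pos + 12L
      } else {
        len <- read_u16(raw, pos + 6L); pos <- pos + 8L
      }
    } else {
      len <- read_u32(raw, pos + 4L); pos <- pos + 8L
    }
    if (len == 4294967295) stopf("unsupported DICOM: undefined-length element %s", key)
    if (pos + len > length(raw)) stopf("corrupt DICOM: element %s overruns file", key)
    tags[[key]] <- raw[seq_len(len) + pos]
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stopf("unsupported DICOM: missing %s", what)
    tags[[key]]
  }
  rows <- read_u16(need("0028,0010", "Rows"), 0L)
  cols <- read_u16(need("0028,0011", "Columns"), 0L)
  bits <- if (is.null(tags[["0028,0100"]])) 8L else read_u16(tags[["0028,0100"]], 0L)
  bits_stored <- if (is.null(tags[["0028,0101"]])) bits else read_u16(tags[["0028,0101"]], 0L)
  signed <- !is.null(tags[["0028,0103"]]) && read_u16(tags[["0028,0103"]], 0L) == 1L
  photo <- if (is.null(tags[["0028,0004"]])) "MONOCHROME2" else
    trimws(rawToChar(tags[["0028,0004"]]))
  spacing <- NULL
  if (!is.null(tags[["0028,0030"]])) {
    parts <- strsplit(trimws(rawToChar(tags[["0028,0030"]])), "\\\\")[[1]]
    spacing <- as.numeric(parts) # DICOM order: row spacing, column spacing
    if (length(spacing) != 2L || any(is.na(spacing)))
      stopf("corrupt DICOM: malformed PixelSpacing")
  }
  pd <- need("7fe0,0010", "PixelData")
  if (bits == 8L) {
    v <- as.integer(pd)[seq_len(rows * cols)]
  } else if (bits == 16L) {
    v <- readBin(pd, "integer", n = rows * cols, size = 2L,
                 endian = "little", signed = signed)
    v[v < 0] <- v[v < 0] + if (signed) 0L else 65536L
    if (bits_stored > 8L) v <- v %/% as.integer(2^(bits_stored - 8L))
  } else stopf("unsupported DICOM: BitsAllocated = %d", bits)
  v <- pmin(pmax(v, 0L), 255L)
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE) # row-major pixel data
  if (identical(photo, "MONOCHROME1")) px <- 255L - px
  list(pixels = px, pixel_spacing_mm = spacing)
}
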