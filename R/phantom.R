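# Seeded synthetic abdominal-ultrasound phantoms with known ground truth.
#
# A phantom emulates the content of a B-mode frame of the anterior abdominal
# wall: fully developed speckle everywhere, two hypoechoic (dark)
# quasi-elliptical rectus abdominis bodies outlined by bright fascia, an
# exactly known lateral gap between them, and optionally a black annotation
# periphery with text-like pixel clusters (raw-frame mode). It stands in for
# clinical data in every test of the pipeline.

#' Specify a synthetic ultrasound phantom
#'
#' @param height_px,width_px image size in pixels.
#' @param pixel_size_mm isotropic pixel size in mm/pixel.
#' @param gap_mm true lateral separation between the inner muscle edges in
#'   mm; 0 produces a single merged muscle region.
#' @param muscle_width_mm,muscle_thickness_mm lateral width and
#'   (axial) thickness of each muscle body in mm.
#' @param n_distractors number of extra small bright/dark blobs scattered in
#'   the background tissue.
#' @param raw_mode if `TRUE`, [generate_phantom()] embeds the scan in a
#'   black periphery with text-like clusters (see [generate_raw_frame()]).
#' @param margin_px periphery margin used when `raw_mode` is `TRUE`.
#' @param seed RNG seed; fixes every random element of the phantom.
#' @return object of class `ra_phantom_spec`.
#' @export
phantom_spec <- function(height_px = 128L, width_px = 128L,
                         pixel_size_mm = 0.5, gap_mm = 10,
                         muscle_width_mm = 16, muscle_thickness_mm = 9,
                         n_distractors = 3L, raw_mode = FALSE,
                         margin_px = 40L, seed = 1L) {
  s <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
            pixel_size_mm = as.numeric(pixel_size_mm), gap_mm = as.numeric(gap_mm),
            muscle_width_mm = as.numeric(muscle_width_mm),
            muscle_thickness_mm = as.numeric(muscle_thickness_mm),
            n_distractors = as.integer(n_distractors),
            raw_mode = isTRUE(raw_mode), margin_px = as.integer(margin_px),
            seed = as.integer(seed))
  if (s$height_px < 16L || s$width_px < 16L)
    stopf("invalid phantom spec: image must be at least 16 x 16 px")
  if (s$pixel_size_mm <= 0) stopf("invalid phantom spec: pixel_size_mm must be positive")
  if (s$gap_mm < 0) stopf("invalid phantom spec: gap_mm must be non-negative")
  if (s$muscle_width_mm <= 0 || s$muscle_thickness_mm <= 0)
    stopf("invalid phantom spec: muscle dimensions must be positive")
  if (s$n_distractors < 0L) stopf("invalid phantom spec: n_distractors must be >= 0")
  if (s$margin_px < 0L) stopf("invalid phantom spec: margin_px must be >= 0")
  if (s$gap_mm + 2 * s$muscle_width_mm >= s$width_px * s$pixel_size_mm)
    stopf("invalid phantom spec: muscles and gap (%.1f mm) do not fit in the %.1f mm field of view",
          s$gap_mm + 2 * s$muscle_width_mm, s$width_px * s$pixel_size_mm)
  if (s$muscle_thickness_mm >= s$height_px * s$pixel_size_mm)
    stopf("invalid phantom spec: muscle thickness exceeds the image depth")
  structure(s, class = "ra_phantom_spec")
}

# separable Gaussian smoothing via the conv kernel (zero padding)
gauss_blur <- function(m, sigma = 1.2, radius = 3L) {
  k <- 2L * radius + 1L
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  K <- outer(g, g) / sum(outer(g, g))
  x4 <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  matrix(cpp_conv_fwd(x4, matrix(as.vector(K), 1L), 0, k), nrow(m), ncol(m))
}

# one muscle body: lens/ellipse with a smooth random radial perturbation,
# rasterized star-shaped (hence connected), trimmed to its bounding box
muscle_patch <- function(a_px, b_px, wobble = 0.06) {
  eps <- runif(3, 0.2, 1) * wobble
  phi <- runif(3, 0, 2 * pi)
  nr <- ceiling(2 * b_px * (1 + 2 * wobble)) + 2L
  nc <- ceiling(2 * a_px * (1 + 2 * wobble)) + 2L
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  u <- outer(rep(1, nr), (seq_len(nc) - cj) / a_px)
  v <- outer((seq_len(nr) - ci) / b_px, rep(1, nc))
  r <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  R <- 1 + eps[1] * cos(2 * th + phi[1]) + eps[2] * cos(3 * th + phi[2]) +
    eps[3] * cos(4 * th + phi[3])
  p <- r <= R
  p[rowSums(p) > 0, colSums(p) > 0, drop = FALSE]
}

place_patch <- function(mask, patch, row0, col0) { # 1-based top-left
  rows <- row0:(row0 + nrow(patch) - 1L)
  cols <- col0:(col0 + ncol(patch) - 1L)
  sub <- mask[rows, cols, drop = FALSE]
  mask[rows, cols] <- pmax(sub, patch * 1L)
  mask
}

#' Generate one synthetic phantom with ground truth
#'
#' Deterministic for a fixed spec (including its seed). The speckle texture
#' is the magnitude of a low-pass-filtered complex Gaussian field, scaled by
#' a per-tissue-class mean so that fascia is brighter than background tissue
#' and the muscle interiors are darker than both. The true pixel gap equals
#' the number of background columns strictly between the two muscle
#' components' column extents; when `gap_mm = 0` the two bodies are merged
#' into a single connected region.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ra_phantom`: `image` (an `ra_frame`), `mask`
#'   (ground-truth binary mask on the same grid), `true_gap_px`,
#'   `true_gap_mm`, `crop_box` (raw mode only; 0-based inclusive rectangle),
#'   `patient_id` (filled by [generate_dataset()]), `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "ra_phantom_spec")) spec <- do.call(phantom_spec, spec)
  set.seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px; px <- spec$pixel_size_mm
  gap_px <- if (spec$gap_mm <= 0) 0L else max(1L, as.integer(round(spec$gap_mm / px)))
  a <- spec$muscle_width_mm / (2 * px)
  b <- spec$muscle_thickness_mm / (2 * px)
  pL <- muscle_patch(a, b)
  pR <- muscle_patch(a, b)

  rjit <- round(rnorm(2, 0, H * 0.02))
  rowL <- min(max(1L, round(H / 2 - nrow(pL) / 2 + rjit[1])), H - nrow(pL) + 1L)
  rowR <- min(max(1L, round(H / 2 - nrow(pR) / 2 + rjit[2])), H - nrow(pR) + 1L)

  mask <- matrix(0L, H, W)
  if (gap_px > 0L) {
    span <- ncol(pL) + gap_px + ncol(pR)
    if (span > W)
      stopf("invalid phantom spec: gap of %d px does not fit laterally", gap_px)
    slack <- W - span
    c0 <- 1L + as.integer(floor(slack / 2)) + as.integer(round(runif(1, -slack / 4, slack / 4)))
    c0 <- min(max(1L, c0), slack + 1L)
    mask <- place_patch(mask, pL, rowL, c0)
    mask <- place_patch(mask, pR, rowR, c0 + ncol(pL) + gap_px)
  } else {
    # merged muscles: overlap the patches until one connected region remains
    ov <- 2L
    repeat {
      span <- ncol(pL) + ncol(pR) - ov
      c0 <- max(1L, as.integer(floor((W - span) / 2)) + 1L)
      mask <- place_patch(matrix(0L, H, W), pL, rowL, c0)
      mask <- place_patch(mask, pR, rowR, c0 + ncol(pL) - ov)
      if (nrow(label_regions(as_mask(mask), 8L)$regions) == 1L) break
      ov <- ov + 2L
      if (ov >= ncol(pR)) stopf("internal error: could not merge muscle bodies")
    }
  }

  # tissue classes: 0 background, 1 muscle interior, 2 fascia outline
  d2 <- cpp_edt_sq(mask, 1, 1)
  fascia <- d2 > 0 & d2 <= 4 # ~2 px bright sheath around each body
  cls <- matrix(0L, H, W)
  cls[fascia] <- 2L
  cls[mask == 1L] <- 1L

  # extra small bright/dark blobs in the background tissue
  distract <- matrix(0, H, W)
  if (spec$n_distractors > 0L) {
    free <- which(cls == 0L & d2 > 36) # keep clear of the muscles
    if (length(free)) {
      ctr <- sample(free, min(spec$n_distractors, length(free)))
      for (p in ctr) {
        i0 <- (p - 1L) %% H + 1L; j0 <- (p - 1L) %/% H + 1L
        rr <- runif(1, 1.5, 4); fac <- sample(c(1.9, 0.45), 1L)
        ii <- pmax(1L, i0 - 5L):pmin(H, i0 + 5L)
        jj <- pmax(1L, j0 - 5L):pmin(W, j0 + 5L)
        blob <- outer((ii - i0)^2, (jj - j0)^2, "+") <= rr^2
        distract[ii, jj][blob & cls[ii, jj] == 0L] <- fac
      }
    }
  }

  # fully developed speckle: magnitude of a smoothed complex Gaussian field
  re <- gauss_blur(matrix(rnorm(H * W), H, W))
  im <- gauss_blur(matrix(rnorm(H * W), H, W))
  mag <- sqrt(re^2 + im^2)
  mag <- mag / mean(mag)
  means <- c(90, 45, 185)[cls + 1L] # background, muscle, fascia
  means[distract > 0] <- 90 * distract[distract > 0]
  img <- clamp255(round(matrix(means, H, W) * mag))

  out <- structure(
    list(image = new_frame(img, px, source_id = sprintf("phantom-seed%d", spec$seed)),
         mask = as_mask(mask, px),
         true_gap_px = gap_px,
         true_gap_mm = gap_px * px,
         crop_box = NULL, patient_id = NA_character_, spec = spec),
    class = "ra_phantom")
  if (spec$raw_mode) out <- generate_raw_frame(out, spec$margin_px, seed = spec$seed + 1L)
  out
}

#' @export
print.ra_phantom <- function(x, ...) {
  cat(sprintf("<ra_phantom: %d x %d px, true gap %d px (%.2f mm)%s>\n",
              nrow(x$image$pixels), ncol(x$image$pixels), x$true_gap_px,
              x$true_gap_mm, if (!is.null(x$crop_box)) ", raw mode" else ""))
  invisible(x)
}

#' Embed a phantom in a raw annotation frame
#'
#' Emulates a frame as exported from the console: the scan region (with the
#' thin bright border the acquisition software draws around the imaging
#' area) sits at a recorded offset inside a black canvas whose periphery
#' carries small bright text-like pixel clusters. Clusters are kept at least
#' 2 px away from the scan region so they remain separate components.
#'
#' @param sample an `ra_phantom` in cropped (non-raw) coordinates.
#' @param margin_px periphery width in pixels on every side.
#' @param seed RNG seed for the cluster layout.
#' @return an `ra_phantom` whose `image`/`mask` are in raw-frame
#'   coordinates, with `crop_box = c(row_min, row_max, col_min, col_max)`
#'   (0-based inclusive) recording the embedded rectangle and attribute
#'   `text_boxes` listing the cluster rectangles.
#' @export
generate_raw_frame <- function(sample, margin_px, seed = 1L) {
  stopifnot(inherits(sample, "ra_phantom"))
  margin_px <- as.integer(margin_px)
  if (is.na(margin_px) || margin_px < 0L) stopf("margin_px must be a non-negative integer")
  if (!is.null(sample$crop_box)) stopf("sample is already a raw frame")
  set.seed(as.integer(seed))
  img <- sample$image$pixels
  H <- nrow(img); W <- ncol(img); m <- margin_px
  img[c(1L, H), ] <- 200L # scan-area border drawn by the console
  img[, c(1L, W)] <- 200L
  canvas <- matrix(0L, H + 2L * m, W + 2L * m)
  canvas[m + seq_len(H), m + seq_len(W)] <- img
  mask <- matrix(0L, H + 2L * m, W + 2L * m)
  mask[m + seq_len(H), m + seq_len(W)] <- sample$mask

  text_boxes <- list()
  if (m >= 10L) {
    n_clusters <- sample(3:7, 1L)
    bands <- list(top = c(1L, m - 2L), bottom = c(m + H + 3L, 2L * m + H),
                  left = c(1L, m - 2L), right = c(m + W + 3L, 2L * m + W))
    for (k in seq_len(n_clusters)) {
      side <- sample(names(bands), 1L)
      hc <- sample(3:6, 1L); wc <- sample(8:24, 1L)
      if (side %in% c("top", "bottom")) {
        rg <- bands[[side]]
        if (rg[2] - rg[1] + 1L < hc) next
        r0 <- sample(rg[1]:(rg[2] - hc + 1L), 1L)
        c0 <- sample(1:(2L * m + W - wc + 1L), 1L)
      } else {
        rg <- bands[[side]]
        if (rg[2] - rg[1] + 1L < wc) next
        c0 <- sample(rg[1]:(rg[2] - wc + 1L), 1L)
        r0 <- sample(1:(2L * m + H - hc + 1L), 1L)
      }
      block <- matrix(ifelse(runif(hc * wc) < 0.45,
                             sample(160:255, hc * wc, replace = TRUE), 0L), hc, wc)
      canvas[r0:(r0 + hc - 1L), c0:(c0 + wc - 1L)] <- block
      text_boxes[[length(text_boxes) + 1L]] <-
        c(row_min = r0 - 1L, row_max = r0 + hc - 2L,
          col_min = c0 - 1L, col_max = c0 + wc - 2L)
    }
  }
  out <- sample
  out$image <- new_frame(canvas, sample$image$pixel_size_mm,
                         source_id = paste0(sample$image$source_id, "-raw"))
  out$mask <- as_mask(mask, attr(sample$mask, "pixel_size_mm"))
  out$crop_box <- c(row_min = m, row_max = m + H - 1L,
                    col_min = m, col_max = m + W - 1L)
  attr(out, "text_boxes") <- text_boxes
  out
}

#' Generate a patient-structured phantom dataset
#'
#' Emulates a clinical collection in which each patient contributes several
#' views: one latent inter-muscle gap is drawn per patient and each of that
#' patient's images jitters it slightly (default 10%), so gaps are
#' correlated within a patient. A fraction of patients has fully merged
#' muscles (gap 0). Deterministic for a fixed seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param images_per_patient integer range `c(lo, hi)`; each patient gets a
#'   uniform draw of images from it.
#' @param gap_range_mm latent gap range for separated patients, in mm.
#' @param p_zero_gap probability that a patient has merged muscles.
#' @param gap_jitter per-image relative jitter of the latent gap.
#' @param seed RNG seed for the whole dataset.
#' @param ... further arguments passed to [phantom_spec()] (image size,
#'   pixel size, muscle dimensions, ...).
#' @return list of `ra_phantom` samples, each with `patient_id` set.
#' @export
generate_dataset <- function(n_patients, images_per_patient = c(4L, 11L),
                             gap_range_mm = c(2, 30), p_zero_gap = 0.2,
                             gap_jitter = 0.1, seed = 1L, ...) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stopf("n_patients must be >= 1")
  rng <- as.integer(images_per_patient)
  if (length(rng) != 2L || any(is.na(rng)) || rng[1] < 1L || rng[2] < rng[1])
    stopf("images_per_patient must be a non-empty range c(lo, hi), lo >= 1")
  base <- phantom_spec(...)
  set.seed(as.integer(seed))
  # stage 1: draw all patient/image-level variables up front
  n_img <- if (rng[1] == rng[2]) rep(rng[1], n_patients) else
    sample(rng[1]:rng[2], n_patients, replace = TRUE)
  latent <- ifelse(runif(n_patients) < p_zero_gap, 0,
                   runif(n_patients, gap_range_mm[1], gap_range_mm[2]))
  plan <- list()
  max_gap <- base$width_px * base$pixel_size_mm - 2 * base$muscle_width_mm * 1.1 -
    4 * base$pixel_size_mm
  for (p in seq_len(n_patients)) {
    for (i in seq_len(n_img[p])) {
      g <- if (latent[p] == 0) 0 else
        min(max(0, latent[p] * (1 + rnorm(1, 0, gap_jitter))), max_gap)
      plan[[length(plan) + 1L]] <- list(
        patient = sprintf("P%03d", p), gap_mm = g,
        width_scale = runif(1, 0.92, 1.08),
        seed = sample.int(.Machine$integer.max - 1L, 1L))
    }
  }
  # stage 2: generate (each phantom reseeds from its own seed)
  lapply(plan, function(pl) {
    sp <- base
    sp$gap_mm <- pl$gap_mm
    sp$muscle_width_mm <- base$muscle_width_mm * pl$width_scale
    sp$seed <- pl$seed
    s <- generate_phantom(sp)
    s$patient_id <- pl$patient
    s
  })
}

#' Write a phantom dataset to disk
#'
#' Images and masks go to `images/` and `masks/` as 8-bit grayscale PNG; a
#' `manifest.csv` records patient id, file paths, calibration and ground
#' truth.
#'
#' @param samples list of `ra_phantom` samples (see [generate_dataset()]).
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img_path <- file.path("images", sprintf("img%04d.png", i))
    msk_path <- file.path("masks", sprintf("msk%04d.png", i))
    write_frame_png(s$image, file.path(dir, img_path))
    write_frame_png(s$mask, file.path(dir, msk_path))
    data.frame(patient_id = s$patient_id, image = img_path, mask = msk_path,
               pixel_size_mm = s$image$pixel_size_mm[2],
               true_gap_px = s$true_gap_px, true_gap_mm = s$true_gap_mm)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
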