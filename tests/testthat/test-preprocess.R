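test_that("PNG frames load with the supplied calibration", {
  dir <- withr::local_tempdir()
  px <- matrix(as.integer(round(seq(0, 255, length.out = 30 * 20))), 30, 20)
  p <- file.path(dir, "gray.png")
  write_frame_png(px, p)
  fr <- load_frame(p, pixel_size_mm = 0.2)
  expect_s3_class(fr, "ra_frame")
  expect_equal(fr$pixel_size_mm, c(0.2, 0.2))
  expect_identical(fr$pixels, px)
  expect_error(load_frame(p), "calibration")
  expect_error(load_frame(file.path(dir, "missing.png"), 0.2), "not found")
})

test_that("an RGB PNG of a gray image loads identically to the gray original", {
  dir <- withr::local_tempdir()
  g <- matrix(runif(25 * 25), 25, 25)
  png::writePNG(g, file.path(dir, "gray.png"))
  png::writePNG(array(rep(g, 3), c(25, 25, 3)), file.path(dir, "rgb.png"))
  a <- load_frame(file.path(dir, "gray.png"), 0.1)
  b <- load_frame(file.path(dir, "rgb.png"), 0.1)
  expect_identical(a$pixels, b$pixels)
})

test_that("DICOM pixel spacing overrides the argument calibration", {
  dir <- withr::local_tempdir()
  px <- matrix(as.integer((0:249) %% 251), 10, 25)
  p <- file.path(dir, "a.dcm")
  write_test_dicom(p, px, spacing = c(0.1, 0.15))
  fr <- load_frame(p, pixel_size_mm = 0.2)
  expect_equal(fr$pixel_size_mm, c(0.1, 0.15))
  expect_identical(fr$pixels, px)
  # no spacing in the file: the argument is used; none at all: error
  p2 <- file.path(dir, "b.dcm")
  write_test_dicom(p2, px)
  expect_equal(load_frame(p2, pixel_size_mm = 0.2)$pixel_size_mm, c(0.2, 0.2))
  expect_error(load_frame(p2), "calibration")
})

test_that("16-bit DICOM pixel data is rescaled to 8 bits", {
  dir <- withr::local_tempdir()
  px8 <- matrix(as.integer(c(0, 17, 130, 255, 64, 200)), 2, 3)
  p <- file.path(dir, "w.dcm")
  # write the same image at 16-bit depth: value * 256 spans the 16-bit range
  write_test_dicom(p, px8 * 256L, spacing = c(0.2, 0.2), bits = 16L)
  expect_identical(load_frame(p)$pixels, px8)
})

test_that("MONOCHROME1 DICOM intensities are inverted to brighter-is-higher", {
  dir <- withr::local_tempdir()
  px <- matrix(as.integer(c(0, 100, 200, 255, 50, 25)), 2, 3)
  p <- file.path(dir, "m1.dcm")
  write_test_dicom(p, px, spacing = c(0.3, 0.3), photometric = "MONOCHROME1")
  expect_identical(load_frame(p)$pixels, 255L - px)
})

test_that("otsu threshold separates a two-level image", {
  px <- matrix(c(rep(0L, 60), rep(255L, 40)), 10, 10)
  t <- otsu_threshold(px)
  expect_gte(t, 0L)
  expect_lt(t, 255L)
  expect_identical(t, brute_otsu(px)) # same tie rule as the oracle
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "degenerate")
})

test_that("otsu equals exhaustive between-class-variance search on random images", {
  set.seed(11)
  for (i in 1:20) {
    px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_identical(otsu_threshold(px), brute_otsu(px))
  }
})

test_that("otsu lands between the modes of a bimodal histogram", {
  set.seed(2)
  v <- as.integer(pmin(pmax(round(c(rnorm(600, 50, 10), rnorm(400, 200, 12))), 0), 255))
  t <- otsu_threshold(matrix(v, 40, 25))
  expect_gt(t, 50L)
  expect_lt(t, 200L)
  expect_identical(t, brute_otsu(v))
})

test_that("strip_periphery crops the largest bright component's rectangle", {
  # two bright rectangles: the larger wins
  px <- matrix(0L, 60, 60)
  px[11:35, 11:50] <- 180L # 25 x 40 = 1000 px
  px[45:49, 45:54] <- 220L # 50 px
  cr <- strip_periphery(new_frame(px, 0.2))
  expect_identical(unname(cr$box), c(10L, 34L, 10L, 49L))
  expect_identical(dim(cr$cropped$pixels), c(25L, 40L))
  expect_equal(cr$cropped$pixel_size_mm, c(0.2, 0.2))
})

test_that("a frame that is entirely scan region crops to itself and crop is idempotent", {
  set.seed(3)
  px <- matrix(as.integer(sample(c(120:255), 400, TRUE)), 20, 20)
  px[1] <- 0L # need two intensity levels
  cr <- strip_periphery(new_frame(px, 0.1))
  expect_identical(unname(cr$box), c(0L, 19L, 0L, 19L))
  cr2 <- strip_periphery(cr$cropped)
  expect_identical(unname(cr2$box), c(0L, 19L, 0L, 19L))
})

test_that("strip_periphery recovers the phantom's recorded crop box", {
  for (seed in c(2, 9)) {
    r <- generate_phantom(phantom_spec(seed = seed, raw_mode = TRUE, margin_px = 35L))
    cr <- strip_periphery(r$image)
    expect_identical(unname(cr$box), unname(r$crop_box))
  }
})

test_that("resize preserves content and tracks per-axis pixel size", {
  set.seed(4)
  px <- matrix(as.integer(sample(0:255, 512 * 512, TRUE)), 512, 512)
  f <- new_frame(px, 0.1)
  same <- resize_to_model(f, 512)
  expect_identical(same$pixels, px) # half-pixel-center convention: identity

  tall <- new_frame(matrix(as.integer(sample(0:255, 1024 * 512, TRUE)), 1024, 512), 0.1)
  out <- resize_to_model(tall, 512)
  expect_equal(out$pixel_size_mm, c(0.2, 0.1)) # row axis compressed 2x
  expect_identical(dim(out$pixels), c(512L, 512L))

  const <- resize_to_model(new_frame(matrix(77L, 100, 300), 0.15), 64)
  expect_true(all(const$pixels == 77L))
})

test_that("physical extent is conserved through resize", {
  set.seed(5)
  for (i in 1:10) {
    h <- sample(50:400, 1)
    w <- sample(50:400, 1)
    ps <- runif(1, 0.05, 0.5)
    f <- new_frame(matrix(as.integer(sample(0:255, h * w, TRUE)), h, w), ps)
    out <- resize_to_model(f, 128)
    expect_equal(128 * out$pixel_size_mm[1], h * ps, tolerance = ps / (h * ps))
    expect_equal(128 * out$pixel_size_mm[2], w * ps, tolerance = ps / (w * ps))
  }
})

test_that("mask resize stays binary and shares the image transform", {
  s <- generate_phantom(phantom_spec(seed = 6))
  m64 <- resize_mask(s$mask, 64)
  expect_true(all(m64 %in% c(0L, 1L)))
  f64 <- resize_to_model(s$image, 64)
  expect_equal(attr(m64, "pixel_size_mm"), f64$pixel_size_mm)
})
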