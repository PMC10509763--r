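test_that("phantom spec validation rejects impossible geometry", {
  expect_error(phantom_spec(gap_mm = -1), "non-negative")
  expect_error(phantom_spec(pixel_size_mm = 0), "positive")
  expect_error(phantom_spec(gap_mm = 60, width_px = 128, pixel_size_mm = 0.5,
                            muscle_width_mm = 16), "fit")
})

test_that("zero gap produces one merged region, positive gap two", {
  s0 <- generate_phantom(phantom_spec(gap_mm = 0, seed = 1))
  expect_identical(nrow(label_regions(s0$mask)$regions), 1L)
  expect_identical(s0$true_gap_px, 0L)

  s1 <- generate_phantom(phantom_spec(gap_mm = 10, seed = 1))
  expect_identical(nrow(label_regions(s1$mask)$regions), 2L)
  expect_gt(s1$true_gap_px, 0L)
})

test_that("true gap in pixels matches the requested physical gap", {
  s <- generate_phantom(phantom_spec(gap_mm = 3.0, pixel_size_mm = 0.25, seed = 7,
                                     width_px = 200, height_px = 128))
  expect_identical(s$true_gap_px, 12L) # 3.0 / 0.25
  expect_equal(s$true_gap_mm, 3.0)
  # oracle: count the empty columns between the two components
  expect_identical(count_gap_columns(s$mask), 12L)
})

test_that("seed changes the texture but not the ground truth", {
  sp1 <- phantom_spec(gap_mm = 8, seed = 1)
  sp2 <- phantom_spec(gap_mm = 8, seed = 2)
  a <- generate_phantom(sp1)
  b <- generate_phantom(sp2)
  expect_false(identical(a$image$pixels, b$image$pixels))
  expect_identical(a$true_gap_px, b$true_gap_px)
  # and the same seed reproduces everything
  expect_identical(generate_phantom(sp1)$image$pixels, a$image$pixels)
})

test_that("tissue class mean intensities are ordered fascia > background > muscle", {
  for (seed in 1:8) {
    s <- generate_phantom(phantom_spec(gap_mm = 12, seed = seed))
    img <- s$image$pixels
    m <- s$mask
    d2 <- raseg:::cpp_edt_sq(m, 1, 1)
    fascia <- d2 > 0 & d2 <= 4
    bg <- d2 > 4
    expect_gt(mean(img[fascia]), mean(img[bg]))
    expect_gt(mean(img[bg]), mean(img[m == 1L]))
  }
})

test_that("raw-frame embedding records the crop box and keeps the periphery black", {
  s <- generate_phantom(phantom_spec(seed = 3))
  r <- generate_raw_frame(s, margin_px = 40L, seed = 9)
  expect_identical(unname(r$crop_box), c(40L, 167L, 40L, 167L))
  expect_identical(dim(r$image$pixels), c(208L, 208L))
  # mask content is preserved, just shifted
  expect_identical(sum(r$mask), sum(s$mask))
  expect_identical(r$true_gap_px, s$true_gap_px)
  # all periphery pixels outside the recorded text clusters are 0
  outside <- matrix(TRUE, 208, 208)
  outside[41:168, 41:168] <- FALSE
  for (tb in attr(r, "text_boxes"))
    outside[(tb["row_min"]:tb["row_max"]) + 1L, (tb["col_min"]:tb["col_max"]) + 1L] <- FALSE
  expect_true(all(r$image$pixels[outside] == 0L))
})

test_that("degenerate margin embeds the frame as the full canvas", {
  s <- generate_phantom(phantom_spec(seed = 4))
  r <- generate_raw_frame(s, margin_px = 0L, seed = 1)
  expect_identical(unname(r$crop_box), c(0L, 127L, 0L, 127L))
  expect_identical(dim(r$image$pixels), dim(s$image$pixels))
})

test_that("dataset generation respects patient structure and the seed contract", {
  ds <- generate_dataset(10, images_per_patient = c(4L, 11L), seed = 5)
  expect_gte(length(ds), 40L)
  expect_lte(length(ds), 110L)
  expect_identical(length(unique(vapply(ds, function(s) s$patient_id, ""))), 10L)

  one <- generate_dataset(1, images_per_patient = c(3L, 3L), seed = 5)
  expect_identical(unique(vapply(one, function(s) s$patient_id, "")), "P001")

  again <- generate_dataset(10, images_per_patient = c(4L, 11L), seed = 5)
  expect_identical(lapply(again, function(s) s$image$pixels),
                   lapply(ds, function(s) s$image$pixels))
  expect_error(generate_dataset(0), "n_patients")
  expect_error(generate_dataset(3, images_per_patient = c(5L, 2L)), "range")
})

test_that("within-patient gaps are correlated across views", {
  ds <- generate_dataset(12, images_per_patient = c(5L, 5L), seed = 42,
                         p_zero_gap = 0)
  gaps <- vapply(ds, function(s) s$true_gap_mm, 0)
  pid <- vapply(ds, function(s) s$patient_id, "")
  within_sd <- mean(tapply(gaps, pid, sd))
  between_sd <- sd(tapply(gaps, pid, mean))
  expect_lt(within_sd, between_sd) # patient identity dominates the jitter
})

test_that("dataset round-trips through the PNG + manifest writer", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, images_per_patient = c(2L, 2L), seed = 1)
  write_dataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 6L)
  fr <- load_frame(file.path(dir, man$image[1]), pixel_size_mm = man$pixel_size_mm[1])
  expect_identical(fr$pixels, ds[[1]]$image$pixels)
  mk <- load_frame(file.path(dir, man$mask[1]), pixel_size_mm = man$pixel_size_mm[1])
  expect_identical(matrix(as.integer(mk$pixels > 0), 128, 128),
                   matrix(as.integer(ds[[1]]$mask), 128, 128))
})
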