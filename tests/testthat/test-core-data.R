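test_that("hs_cube validates its invariants", {
  expect_error(hs_cube(array(0, c(3, 3, 2)), c(500, 400)),
               "strictly increasing")
  expect_error(hs_cube(array(0, c(3, 3, 2)), c(500, 600, 700)),
               "band count")
  expect_error(hs_cube(array(0, c(1, 3, 2)), c(500, 600)), "2x2")
  cube <- random_cube()
  expect_s3_class(cube, "hs_cube")
  expect_identical(dim(cube), dim(cube$data))
})

test_that("ENVI round trip is exact for every interleave", {
  cube <- float32_cube()
  for (il in c("bsq", "bil", "bip")) {
    p <- tempfile()
    write_envi(cube, p, interleave = il)
    back <- read_envi(p)
    expect_identical(back$data, cube$data, label = paste("data", il))
    expect_equal(back$wavelengths, cube$wavelengths, tolerance = 1e-4)
  }
  # float64 preserves arbitrary doubles bit-exactly
  cube64 <- random_cube()
  p <- tempfile()
  write_envi(cube64, p, data_type = 5L)
  expect_identical(read_envi(p)$data, cube64$data)
})

test_that("ENVI header declares dimensions in the ENVI convention", {
  cube <- float32_cube(rows = 4, cols = 3, bands = 5)
  p <- tempfile()
  write_envi(cube, p)
  hdr <- readLines(paste0(p, ".hdr"))
  expect_true("samples = 3" %in% hdr)
  expect_true("lines = 4" %in% hdr)
  expect_true("bands = 5" %in% hdr)
  expect_match(hdr[grep("wavelength =", hdr)], "435.0000")
})

test_that("contradictory or missing header fields raise named errors", {
  cube <- float32_cube()
  p <- tempfile()
  write_envi(cube, p)
  hdr <- readLines(paste0(p, ".hdr"))
  writeLines(sub("bands = 5", "bands = 4", hdr), paste0(p, ".hdr"))
  expect_error(read_envi(p), "4 bands but lists 5 wavelengths")
  writeLines(hdr[!grepl("^samples", hdr)], paste0(p, ".hdr"))
  expect_error(read_envi(p), "samples")
  expect_error(read_envi(tempfile()), "header not found")
})

test_that("calibration maps raw counts onto the white-dark scale", {
  set.seed(3)
  d <- c(5, 4, 6)
  dark <- array(runif(prod(d), 0, 0.1), d)
  white <- dark + array(runif(prod(d), 0.5, 1), d)
  w <- seq(500, 550, length.out = d[3])
  as_cube <- function(a) hs_cube(a, w)
  expect_equal(calibrate(as_cube(white), white, dark)$data,
               array(1, d))
  expect_equal(calibrate(as_cube(dark), white, dark)$data, array(0, d))
  mid <- dark + 0.5 * (white - dark)
  expect_equal(calibrate(as_cube(mid), white, dark)$data,
               array(0.5, d), tolerance = 1e-12)
})

test_that("calibration is invariant to affine sensor re-scaling", {
  set.seed(4)
  d <- c(4, 4, 5)
  dark <- array(runif(prod(d), 0, 0.1), d)
  white <- dark + array(runif(prod(d), 0.4, 1), d)
  raw <- dark + array(runif(prod(d)), d) * (white - dark)
  w <- seq(500, 540, length.out = d[3])
  r1 <- calibrate(hs_cube(raw, w), white, dark)
  r2 <- calibrate(hs_cube(3.7 * raw + 2, w), 3.7 * white + 2,
                  3.7 * dark + 2)
  expect_equal(r1$data, r2$data, tolerance = 1e-9)
})

test_that("degenerate white-dark elements are floored with a warning", {
  d <- c(5, 5, 4)
  dark <- array(0.1, d)
  white <- array(0.9, d)
  white[1, 1, 1] <- 0.1   # one dead element, still within sensor sanity
  raw <- array(0.5, d)
  w <- c(500, 510, 520, 530)
  expect_warning(out <- calibrate(hs_cube(raw, w), white, dark),
                 "floored")
  expect_true(all(is.finite(out$data)))
  expect_true(all(out$data >= 0 & out$data <= 2))
  expect_identical(out$meta$n_degenerate, 1L)
  # swapped references trip the sanity check
  expect_error(calibrate(hs_cube(raw, w), dark, white), "swapped")
})

test_that("spectral smoothing acts along bands only", {
  cube <- random_cube(bands = 9)
  expect_identical(smooth_spectra(cube, 1L)$data, cube$data)
  expect_error(smooth_spectra(cube, 4L), "odd")
  const <- hs_cube(array(0.7, c(3, 3, 9)), cube$wavelengths)
  expect_equal(smooth_spectra(const, 5L)$data, const$data)
  # unit impulse spreads as the closed-form moving-average kernel
  imp <- array(0, c(2, 2, 9)); imp[1, 1, 5] <- 1
  sm <- smooth_spectra(hs_cube(imp, cube$wavelengths), 3L)
  expect_equal(sm$data[1, 1, ], c(0, 0, 0, 1/3, 1/3, 1/3, 0, 0, 0))
  expect_equal(sm$data[2, 2, ], rep(0, 9))
  # interior bands equal the hand-computed symmetric moving average
  set.seed(5)
  spec9 <- runif(9)
  cube1 <- hs_cube(array(rep(spec9, each = 4), c(2, 2, 9)),
                   cube$wavelengths)
  sm2 <- smooth_spectra(cube1, 3L)
  hand <- (spec9[1:7] + spec9[2:8] + spec9[3:9]) / 3
  expect_equal(sm2$data[1, 1, 2:8], hand, tolerance = 1e-9)
})

test_that("band cropping keeps the closed wavelength interval", {
  cube <- hs_cube(array(runif(4 * 4 * 4), c(4, 4, 4)), 1:4 * 100)
  expect_equal(n_bands_of(crop_bands(cube, 200, 300)), 2L)
  expect_identical(crop_bands(cube, 100, 400)$data, cube$data)
  # grid-enumeration oracle on the realistic VNIR grid
  w <- seq(400, 1000, by = 0.727)
  big <- hs_cube(array(0.5, c(2, 2, length(w))), w)
  cropped <- crop_bands(big, 435, 901)
  expect_identical(n_bands_of(cropped), sum(w >= 435 & w <= 901))
  # widening re-crop is a no-op
  expect_identical(crop_bands(cropped, 400, 1000)$data, cropped$data)
  expect_error(crop_bands(cube, 450, 460), "fewer than 2 bands")
})

test_that("pseudo-RGB and grayscale rendering behave as configured", {
  const <- hs_cube(array(0.4, c(3, 3, 5)), seq(450, 750, length.out = 5))
  rgb <- pseudo_rgb(const)
  expect_true(all(rgb == 0.5))   # constant planes render mid-gray
  cube <- random_cube(bands = 5)
  rgb2 <- pseudo_rgb(cube, bands_nm = cube$wavelengths[c(5, 3, 1)])
  for (k in 1:3) {
    plane <- cube$data[, , c(5, 3, 1)[k]]
    expect_equal(rgb2[, , k],
                 (plane - min(plane)) / (max(plane) - min(plane)))
  }
  # NIR false color: one band replicated across channels
  nir <- random_cube(bands = 5, modality = "NIR")
  nir$wavelengths <- seq(900, 1700, length.out = 5)
  rgb3 <- pseudo_rgb(nir)
  expect_identical(rgb3[, , 1], rgb3[, , 2])
  expect_identical(rgb3[, , 2], rgb3[, , 3])
  # grayscale: luminance weights, idempotent on gray input
  g <- matrix(runif(9), 3, 3)
  gray_in <- array(rep(g, 3), c(3, 3, 3))
  expect_equal(to_grayscale(gray_in), g, tolerance = 1e-12)
  red <- array(0, c(3, 3, 3)); red[, , 1] <- g
  expect_equal(to_grayscale(red), 0.299 * g)
})

test_that("per-pixel min-max normalization hits 0 and 1 at every pixel", {
  cube <- hs_cube(array(c(rep(2, 4), rep(4, 4), rep(6, 4)), c(2, 2, 3)),
                  c(500, 600, 700))
  norm <- minmax_normalize_pixels(cube)
  expect_equal(norm$data[1, 1, ], c(0, 0.5, 1))
  rnd <- minmax_normalize_pixels(random_cube(seed = 6))
  flat <- matrix(rnd$data, prod(dim(rnd$data)[1:2]), dim(rnd$data)[3])
  expect_equal(apply(flat, 1, min), rep(0, nrow(flat)))
  expect_equal(apply(flat, 1, max), rep(1, nrow(flat)))
  # constant pixel: zeros plus a warning
  cc <- random_cube(seed = 7)
  cc$data[1, 1, ] <- 0.3
  expect_warning(out <- minmax_normalize_pixels(cc), "constant")
  expect_equal(out$data[1, 1, ], rep(0, dim(cc$data)[3]))
})

test_that("label maps round trip through PNG + JSON", {
  set.seed(8)
  lm <- label_map(matrix(sample(0:3, 30, replace = TRUE), 5, 6),
                  c("a", "b", "c"))
  p <- tempfile()
  write_label_map(lm, p)
  back <- read_label_map(p)
  expect_identical(back$labels, lm$labels)
  expect_identical(back$class_names, lm$class_names)
  expect_error(label_map(matrix(5, 3, 3), c("a", "b")), "exceeds")
})
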