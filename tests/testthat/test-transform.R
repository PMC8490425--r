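random_transform <- function(kind, seed) {
  set.seed(seed)
  th <- runif(1, -0.1, 0.1); s <- runif(1, 0.9, 1.1)
  base <- switch(kind,
    translation = rbind(c(1, 0, runif(1, -5, 5)),
                        c(0, 1, runif(1, -5, 5)), c(0, 0, 1)),
    similarity = rbind(c(s * cos(th), -s * sin(th), runif(1, -5, 5)),
                       c(s * sin(th), s * cos(th), runif(1, -5, 5)),
                       c(0, 0, 1)),
    affine = rbind(c(1 + runif(1, -0.1, 0.1), runif(1, -0.1, 0.1),
                     runif(1, -5, 5)),
                   c(runif(1, -0.1, 0.1), 1 + runif(1, -0.1, 0.1),
                     runif(1, -5, 5)), c(0, 0, 1)),
    projective = rbind(c(1 + runif(1, -0.1, 0.1), runif(1, -0.1, 0.1),
                         runif(1, -5, 5)),
                       c(runif(1, -0.1, 0.1), 1 + runif(1, -0.1, 0.1),
                         runif(1, -5, 5)),
                       c(runif(1, -1e-4, 1e-4), runif(1, -1e-4, 1e-4),
                         1)))
  transform_model(kind, base)
}

test_that("transform kinds constrain the matrix shape", {
  proj <- rbind(c(1, 0, 0), c(0, 1, 0), c(1e-4, 0, 1))
  expect_error(transform_model("affine", proj), "bottom row")
  expect_s3_class(transform_model("projective", proj), "transform_model")
  expect_error(transform_model("affine", matrix(0, 3, 3)), "singular")
})

test_that("least-squares fits recover exact generating transforms", {
  set.seed(61)
  pts <- cbind(runif(25, 1, 100), runif(25, 1, 100))
  for (kind in c("translation", "similarity", "affine", "projective")) {
    truth <- random_transform(kind, seed = 60 + nchar(kind))
    fitted <- fit_transform(apply_transform(truth, pts), pts, kind)
    expect_lt(frobenius_after_scale(fitted$matrix, truth$matrix), 1e-6)
  }
  expect_error(fit_transform(pts[1:2, ], pts[1:2, ], "affine"),
               "at least 3")
})

test_that("apply and invert compose to the identity", {
  tm <- random_transform("projective", 62)
  pts <- cbind(runif(10, 1, 50), runif(10, 1, 50))
  back <- apply_transform(invert_transform(tm), apply_transform(tm, pts))
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("warping matches exact pixel arithmetic", {
  set.seed(63)
  img <- matrix(runif(40 * 40), 40, 40)
  ident <- transform_model("affine", diag(3))
  expect_equal(warp_image(img, ident)$image, img, tolerance = 1e-12)
  # integer translation is an exact pixel shift
  shift <- transform_model("translation",
                           rbind(c(1, 0, 3), c(0, 1, 2), c(0, 0, 1)))
  w <- warp_image(img, shift)
  expect_equal(w$image[3:40, 4:40], img[1:38, 1:37], tolerance = 1e-12)
  expect_false(any(w$mask[1:2, ]))
  # warp then inverse-warp returns close to the original on the interior
  # (a band-limited image, where the interpolation error is small)
  smooth_img <- as.matrix(EBImage::gblur(img, sigma = 2))
  th <- 2 * pi / 180; c0 <- 20.5
  tm <- transform_model("projective",
                        rbind(c(cos(th), -sin(th),
                                c0 * (1 - cos(th)) + c0 * sin(th) + 1.3),
                              c(sin(th), cos(th),
                                c0 * (1 - cos(th)) - c0 * sin(th) - 0.7),
                              c(1e-5, -1e-5, 1)))
  fwd <- warp_image(smooth_img, tm, fill = 0)
  back <- warp_image(fwd$image, invert_transform(tm), fill = 0)
  interior <- 6:35
  # bound: twice the worst-case bilinear round-trip error, measured on
  # this image with a half-pixel shift there and back
  half <- transform_model("translation",
                          rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0, 0, 1)))
  shifted <- warp_image(smooth_img, half)$image
  undone <- warp_image(shifted, invert_transform(half))$image
  interp_bound <- mean(abs(undone[interior, interior] -
                           smooth_img[interior, interior]))
  expect_lt(mean(abs(back$image[interior, interior] -
                     smooth_img[interior, interior])), 2 * interp_bound)
})

test_that("cube warping shares geometry across bands", {
  cube <- random_cube(rows = 20, cols = 20, bands = 3, seed = 65)
  shift <- transform_model("translation",
                           rbind(c(1, 0, 2), c(0, 1, 0), c(0, 0, 1)))
  w <- warp_cube(cube, shift)
  for (b in 1:3)
    expect_equal(w$cube$data[, 3:20, b], cube$data[, 1:18, b],
                 tolerance = 1e-12)
})

# brute-force largest-rectangle oracle using a summed-area table
brute_rectangle <- function(mask) {
  cs <- apply(apply(mask, 2, cumsum), 1, cumsum)  # transposed SAT
  total <- function(r1, r2, c1, c2) {
    s <- cs[c2, r2]
    if (r1 > 1) s <- s - cs[c2, r1 - 1]
    if (c1 > 1) s <- s - cs[c1 - 1, r2]
    if (r1 > 1 && c1 > 1) s <- s + cs[c1 - 1, r1 - 1]
    s
  }
  best <- 0
  for (r1 in 1:nrow(mask)) for (r2 in r1:nrow(mask))
    for (c1 in 1:ncol(mask)) for (c2 in c1:ncol(mask)) {
      area <- (r2 - r1 + 1) * (c2 - c1 + 1)
      if (area > best && total(r1, r2, c1, c2) == area) best <- area
    }
  best
}

test_that("common-ROI cropping finds the maximal valid rectangle", {
  cube <- random_cube(rows = 12, cols = 12, bands = 2, seed = 66)
  full <- matrix(TRUE, 12, 12)
  out <- crop_common_roi(cube, cube, full)
  expect_identical(out$roi, c(1L, 12L, 1L, 12L))
  # mask missing the top rows drops exactly those rows
  part <- full; part[1:3, ] <- FALSE
  out2 <- crop_common_roi(cube, cube, part)
  expect_identical(out2$roi, c(4L, 12L, 1L, 12L))
  expect_identical(out2$fixed$data, cube$data[4:12, , , drop = FALSE])
  # maximality against brute force on random masks
  set.seed(67)
  for (i in 1:5) {
    mask <- matrix(runif(16 * 16) > 0.25, 16, 16)
    roi <- largest_true_rectangle(mask)
    area <- (roi[2] - roi[1] + 1) * (roi[4] - roi[3] + 1)
    expect_true(all(mask[roi[1]:roi[2], roi[3]:roi[4]]))
    expect_identical(area, brute_rectangle(mask))
  }
})

test_that("transforms serialize losslessly to JSON", {
  tm <- random_transform("projective", 68)
  tm$provenance <- list(technique = "features", seed = 5L)
  p <- tempfile(fileext = ".json")
  write_transform(tm, p)
  back <- read_transform(p)
  expect_equal(back$matrix, tm$matrix, tolerance = 1e-12)
  expect_identical(back$kind, tm$kind)
})
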