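test_that("generators are pure functions of spec and seed", {
  spec <- scene_spec(vnir_dims = c(16, 16), nir_dims = c(16, 16),
                     seed = 11)
  expect_identical(make_reference_panel(spec), make_reference_panel(spec))
  spec2 <- scene_spec(vnir_dims = c(32, 32), seed = 12)
  expect_identical(make_registration_target(spec2)$vnir$data,
                   make_registration_target(spec2)$vnir$data)
  spec3 <- scene_spec(vnir_dims = c(48, 48), nir_dims = c(24, 24),
                      seed = 13)
  expect_identical(make_plastic_scene(spec3)$vnir$data,
                   make_plastic_scene(spec3)$vnir$data)
})

test_that("sensor capture adds the configured band-dependent noise", {
  w <- seq(500, 600, length.out = 10)
  ideal <- hs_cube(array(0.5, c(64, 64, 10)), w)
  # zero profile: identity
  expect_identical(sensor_capture(ideal, rep(0, 10), 1)$data, ideal$data)
  # sample std per band within 10% of the profile
  prof <- seq(0.02, 0.08, length.out = 10)
  cap <- sensor_capture(ideal, prof, 42)
  resid <- cap$data - ideal$data
  sds <- apply(matrix(resid, 64 * 64, 10), 2, sd)
  expect_true(all(abs(sds - prof) / prof < 0.1))
  # different seeds give different captures of the same ideal
  expect_false(identical(cap$data, sensor_capture(ideal, prof, 43)$data))
})

test_that("reference panels record the clean-band truth of their noise", {
  spec <- scene_spec(vnir_dims = c(16, 16), nir_dims = c(16, 16),
                     edge_frac = 0.05, seed = 21)
  panel <- make_reference_panel(spec)
  nb_v <- n_bands_of(panel$vnir)
  n_edge <- floor(0.05 * nb_v)
  expect_identical(panel$meta$vnir_cut_idx,
                   c(n_edge + 1L, nb_v - n_edge))
  # zero-noise spec: both captures identical, RD identically zero
  clean <- scene_spec(vnir_dims = c(16, 16), nir_dims = c(16, 16),
                      base_sd = 0, seed = 22)
  pc <- make_reference_panel(clean)
  expect_identical(pc$vnir$data, pc$vnir_repeat$data)
  expect_true(all(relative_difference(pc$vnir, pc$vnir_repeat)$rd_mean
                  == 0))
})

test_that("registration targets reproduce their stored geometry", {
  # identity transform, equal dims: NIR layout equals VNIR layout
  ident <- transform_model("affine", diag(3))
  spec <- scene_spec(vnir_dims = c(48, 48), base_sd = 0,
                     true_transform = ident, seed = 31)
  sc <- make_registration_target(spec)
  expect_equal(gray_from_cube(sc$vnir, band = 60),
               gray_from_cube(sc$nir, band = 30), tolerance = 1e-6)
  # pure translation: control points offset exactly
  shift <- transform_model("translation",
                           rbind(c(1, 0, 10), c(0, 1, -7), c(0, 0, 1)))
  spec2 <- scene_spec(vnir_dims = c(64, 64), base_sd = 0,
                      true_transform = shift, seed = 32)
  sc2 <- make_registration_target(spec2)
  cp <- sc2$meta$control_points
  expect_equal(cp$vnir, cp$nir + rep(c(10, -7), each = nrow(cp$nir)))
  # random projective truth maps stored correspondences exactly
  spec3 <- scene_spec(vnir_dims = c(64, 64), seed = 33)
  sc3 <- make_registration_target(spec3)
  cp3 <- sc3$meta$control_points
  mapped <- apply_transform(sc3$true_transform, cp3$nir)
  expect_lt(max(abs(mapped - cp3$vnir)), 0.01)
})

test_that("a transform that misses the NIR frame is rejected", {
  off <- transform_model("translation",
                         rbind(c(1, 0, 1e5), c(0, 1, 1e5), c(0, 0, 1)))
  spec <- scene_spec(vnir_dims = c(32, 32), true_transform = off,
                     seed = 34)
  expect_error(make_registration_target(spec), "outside the NIR frame")
})

test_that("plastic scenes separate color in VNIR and material in NIR", {
  spec <- scene_spec(vnir_dims = c(64, 64), nir_dims = c(32, 32),
                     seed = 41)
  sc <- make_plastic_scene(spec, n_objects = 6L)
  col <- sc$color_gt$labels; mat <- sc$material_gt$labels
  mc <- sc$material_color_gt$labels
  # material-color pairing is bijective over present combinations
  combo <- paste(mat[mc > 0], col[mc > 0])
  expect_identical(length(unique(combo)), length(unique(mc[mc > 0])))
  expect_true(all(tapply(combo, mc[mc > 0],
                         function(x) length(unique(x)) == 1L)))
  # the construction forces collisions both ways
  per_mat_colors <- tapply(col[mc > 0], mat[mc > 0],
                           function(x) length(unique(x)))
  per_col_mats <- tapply(mat[mc > 0], col[mc > 0],
                         function(x) length(unique(x)))
  expect_true(any(per_mat_colors > 1))
  expect_true(any(per_col_mats > 1))
  # regions sharing a material are indistinguishable in the NIR range:
  # their mean NIR-band spectra agree within the generator variability
  nir_mean <- function(m, cl) {
    sel <- mat == m & col == cl
    colMeans(matrix(sc$vnir$data[, , sc$vnir$wavelengths > 956],
                    64 * 64, sum(sc$vnir$wavelengths > 956))[sel, ,
                                                             drop = FALSE])
  }
  m1c <- sort(unique(col[mat == 1]))
  expect_lt(max(abs(nir_mean(1, m1c[1]) - nir_mean(1, m1c[2]))), 0.06)
  # and regions sharing a color collide in the visible range
  vis_mean <- function(m, cl) {
    sel <- mat == m & col == cl
    colMeans(matrix(sc$vnir$data[, , sc$vnir$wavelengths < 900],
                    64 * 64, sum(sc$vnir$wavelengths < 900))[sel, ,
                                                             drop = FALSE])
  }
  c1m <- sort(unique(mat[col == 1]))
  expect_lt(max(abs(vis_mean(c1m[1], 1) - vis_mean(c1m[2], 1))), 0.06)
})

test_that("overfull canvases are rejected", {
  spec <- scene_spec(vnir_dims = c(16, 16), nir_dims = c(16, 16),
                     seed = 42)
  expect_error(make_plastic_scene(spec, n_objects = 40L), "too many")
})

test_that("scene pairs round trip through the on-disk manifest", {
  spec <- scene_spec(vnir_dims = c(16, 16), nir_dims = c(16, 16),
                     seed = 43)
  sc <- make_plastic_scene(spec, n_objects = 4L)
  dir <- tempfile()
  write_scene_pair(sc, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(matrix(man$true_transform, 3, 3, byrow = TRUE),
               sc$true_transform$matrix, tolerance = 1e-12)
  back <- read_envi(file.path(dir, "vnir"))
  expect_equal(back$data, sc$vnir$data, tolerance = 1e-7)
  gt <- read_label_map(file.path(dir, "color_gt"))
  expect_identical(gt$labels, sc$color_gt$labels)
})
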