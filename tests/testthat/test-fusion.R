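flat_pair <- function(seed = 101, dims = c(24, 24)) {
  make_reference_panel(scene_spec(vnir_dims = dims, nir_dims = dims,
                                  seed = seed))
}

test_that("the RD statistic matches its defining formula", {
  cube <- random_cube(rows = 4, cols = 4, bands = 5, seed = 100)
  # identical captures: RD identically zero
  expect_true(all(relative_difference(cube, cube)$rd_mean == 0))
  # hand computation under the mean-normalized formula
  a <- hs_cube(array(1.1, c(2, 2, 2)), c(500, 510))
  b <- hs_cube(array(0.9, c(2, 2, 2)), c(500, 510))
  expect_equal(relative_difference(a, b)$rd_mean, c(20, 20))
  # zero-sum elements are excluded and counted
  a0 <- a; b0 <- b
  a0$data[1, 1, 1] <- 0; b0$data[1, 1, 1] <- 0
  rd <- relative_difference(a0, b0)
  expect_identical(rd$n_excluded, 1L)
  expect_equal(rd$rd_mean, c(20, 20))
})

test_that("noisy spectral extremes push RD above its band average", {
  panel <- flat_pair()
  rd <- relative_difference(panel$vnir, panel$vnir_repeat)
  expect_equal(rd$average_rd_mean, mean(rd$rd_mean), tolerance = 1e-9)
  cut <- panel$meta$vnir_cut_idx
  edges <- c(seq_len(cut[1] - 1), seq(cut[2] + 1, length(rd$rd_mean)))
  interior <- seq(cut[1], cut[2])
  expect_true(all(rd$rd_mean[edges] > rd$average_rd_mean))
  expect_true(mean(rd$rd_mean[interior] < rd$average_rd_mean) > 0.99)
})

test_that("cutoff scanning implements the run-length threshold rule", {
  # constant curve: whole bandwidth retained
  w <- seq(400, 1000, length.out = 120)
  flatc <- rd_curve(w, rep(1, 120))
  cf <- find_cutoffs(flatc)
  expect_identical(c(cf$initial_idx, cf$final_idx), c(1L, 120L))
  # bathtub with elevation on the first/last 20 bands
  bath <- rd_curve(w, c(rep(120, 20), rep(1, 80), rep(120, 20)))
  cb <- find_cutoffs(bath)
  expect_identical(c(cb$initial_idx, cb$final_idx), c(21L, 100L))
  expect_equal(cb$initial_nm, w[21])
  # scale invariance: threshold scales with the curve
  cb2 <- find_cutoffs(rd_curve(w, 7.3 * bath$rd_mean))
  expect_identical(c(cb2$initial_idx, cb2$final_idx), c(21L, 100L))
  # a curve that never settles fails with a diagnostic
  expect_error(find_cutoffs(rd_curve(w[1:8], c(9, 0, 9, 0, 9, 0, 9, 0),
                                     NULL), run_length = 3),
               "no run")
})

test_that("cutoffs recover the injected sensor truth from repeats", {
  hits <- 0L
  for (s in 1:20) {
    panel <- flat_pair(seed = 200 + s, dims = c(16, 16))
    cv <- find_cutoffs(relative_difference(panel$vnir,
                                           panel$vnir_repeat))
    tv <- panel$meta$vnir_cut_idx
    hits <- hits + (abs(cv$initial_idx - tv[1]) <= 2 &&
                      abs(cv$final_idx - tv[2]) <= 2)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("bilinear upsampling reproduces analytic ramps exactly", {
  # constant band stays constant
  const <- hs_cube(array(0.3, c(8, 8, 2)), c(900, 1000))
  up <- upsample_bilinear(const, c(21, 19))
  expect_true(all(abs(up$data - 0.3) < 1e-12))
  # a bilinear ramp a + b x + c y + d x y is reproduced at every target
  # coordinate under the corner-aligned mapping
  src <- c(16, 16); tgt <- c(47, 43)
  xs <- matrix(rep(1:src[2], each = src[1]), src[1], src[2])
  ys <- matrix(rep(1:src[1], src[2]), src[1], src[2])
  ramp <- 0.1 + 0.02 * xs + 0.03 * ys + 0.001 * xs * ys
  cube <- hs_cube(array(ramp, c(src, 2)), c(900, 1000))
  up2 <- upsample_bilinear(cube, tgt)
  tx <- (seq_len(tgt[2]) - 1) * (src[2] - 1) / (tgt[2] - 1) + 1
  ty <- (seq_len(tgt[1]) - 1) * (src[1] - 1) / (tgt[1] - 1) + 1
  xg <- matrix(rep(tx, each = tgt[1]), tgt[1], tgt[2])
  yg <- matrix(rep(ty, tgt[2]), tgt[1], tgt[2])
  analytic <- 0.1 + 0.02 * xg + 0.03 * yg + 0.001 * xg * yg
  expect_lt(max(abs(up2$data[, , 1] - analytic)), 1e-6)
  expect_error(upsample_bilinear(cube, c(8, 8)), "downsampling")
})

test_that("upsampling maps the NIR frame onto the VNIR pixel grid", {
  cube <- hs_cube(array(runif(320 * 253 * 2), c(320, 253, 2)),
                  c(900, 1000), "NIR")
  up <- upsample_bilinear(cube, c(939, 743))
  expect_identical(dim(up$data)[1:2], c(939L, 743L))
})

test_that("label transfer is categorical and conservative", {
  set.seed(102)
  lm <- label_map(matrix(sample(0:3, 20 * 18, replace = TRUE), 20, 18),
                  c("a", "b", "c"))
  expect_identical(transfer_labels(lm, c(20, 18)), lm)
  up <- transfer_labels(lm, c(39, 35))   # doubled grid (2d - 1)
  expect_true(all(unique(as.vector(up$labels)) %in%
                    unique(as.vector(lm$labels))))
  # corner-aligned: original sample sites keep their labels
  expect_identical(up$labels[seq(1, 39, by = 2), seq(1, 35, by = 2)],
                   lm$labels)
})

test_that("the reflectance offset levels the segment junction", {
  vn <- c(0.5, 0.52, 0.48, 0.5, 0.51)
  nr <- vn - 0.1
  expect_equal(reflectance_offset(vn, nr, 5), 0.1, tolerance = 1e-12)
  expect_equal(reflectance_offset(vn, vn, 5), 0)
  # linearity: shifting the NIR spectrum by c changes the offset by -c
  expect_equal(reflectance_offset(vn, nr + 0.07, 5),
               reflectance_offset(vn, nr, 5) - 0.07, tolerance = 1e-12)
  expect_error(reflectance_offset(vn, nr, 9), "exceeds")
})

test_that("fusion conserves bands, gap and normalization", {
  panel <- flat_pair(seed = 103)
  vn <- panel$vnir; nr <- panel$nir
  cv <- find_cutoffs(relative_difference(vn, panel$vnir_repeat))
  cn <- find_cutoffs(relative_difference(nr, panel$nir_repeat))
  fc <- fuse(vn, nr, cv, cn)
  nv <- cv$final_idx - cv$initial_idx + 1L
  nn <- cn$final_idx - cn$initial_idx + 1L
  expect_identical(n_bands_of(fc$cube), nv + nn)
  expect_identical(fc$segment_boundary, nv + 1L)
  w <- fc$cube$wavelengths
  expect_true(all(diff(w) > 0))
  expect_false(any(w > fc$gap_nm[1] & w < fc$gap_nm[2]))
  # per-pixel normalization: min 0, max 1 everywhere
  flat <- matrix(fc$cube$data, prod(dim(fc$cube$data)[1:2]),
                 n_bands_of(fc$cube))
  expect_equal(apply(flat, 1, min), rep(0, nrow(flat)))
  expect_equal(apply(flat, 1, max), rep(1, nrow(flat)))
})

test_that("the fused flat-panel spectrum is continuous at the boundary", {
  panel <- flat_pair(seed = 104)
  cv <- find_cutoffs(relative_difference(panel$vnir, panel$vnir_repeat))
  cn <- find_cutoffs(relative_difference(panel$nir, panel$nir_repeat))
  fc <- fuse(panel$vnir, panel$nir, cv, cn, normalize = FALSE)
  b <- fc$segment_boundary
  flat <- matrix(fc$cube$data, prod(dim(fc$cube$data)[1:2]),
                 n_bands_of(fc$cube))
  edge_jump <- abs(rowMeans(flat[, (b - 3):(b - 1)]) -
                     rowMeans(flat[, b:(b + 2)]))
  expect_lt(mean(edge_jump), 3 * 0.01)   # within the sensor noise scale
})

test_that("overlapping retained ranges are rejected", {
  panel <- flat_pair(seed = 105)
  cv <- fixed_cutoffs(panel$vnir$wavelengths, 435, 990)
  cn <- fixed_cutoffs(panel$nir$wavelengths, 910, 1638)
  expect_error(fuse(panel$vnir, panel$nir, cv, cn), "overlap")
})
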