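#' Absolute relative difference between two repeat captures
#'
#' For two captures of the same static scene, the per-element absolute
#' relative difference percentage is
#' `RD = 100 * |a - b| / ((a + b) / 2)`, symmetric in the two captures.
#' `rd_mean` averages RD over all pixels at each band and exposes the
#' band-dependent repeatability of the sensor; `average_rd_mean` (its band
#' mean) is the threshold the cutoff rule scans against. Elements where
#' `a + b = 0` are excluded and counted.
#'
#' @param capture1,capture2 `hs_cube`s of the same scene on the same grid.
#' @return list of class `rd_curve`: `wavelengths`, `rd_mean`, `rd_std`
#'   (percent), `average_rd_mean`, `n_excluded`.
#' @export
relative_difference <- function(capture1, capture2) {
  if (!all(dim(capture1$data) == dim(capture2$data)))
    stop("captures must share dimensions")
  if (max(abs(capture1$wavelengths - capture2$wavelengths)) > 1e-9)
    stop("captures must share the wavelength grid")
  a <- capture1$data; b <- capture2$data
  mean_ab <- (a + b) / 2
  rd <- 100 * abs(a - b) / mean_ab
  excluded <- mean_ab == 0
  rd[excluded] <- NA_real_
  d <- dim(a)
  flat <- base::matrix(rd, d[1] * d[2], d[3])
  rd_mean <- colMeans(flat, na.rm = TRUE)
  rd_std <- apply(flat, 2L, stats::sd, na.rm = TRUE)
  structure(list(wavelengths = capture1$wavelengths,
                 rd_mean = rd_mean, rd_std = rd_std,
                 average_rd_mean = mean(rd_mean),
                 n_excluded = sum(excluded)),
            class = "rd_curve")
}

#' @export
print.rd_curve <- function(x, ...) {
  cat(sprintf("<rd_curve> %d bands, Average RD_mean = %.3f%%\n",
              length(x$rd_mean), x$average_rd_mean))
  invisible(x)
}

#' Construct an RD curve directly from values
#' @param wavelengths band centers (nm).
#' @param rd_mean per-band mean RD (percent).
#' @param rd_std optional per-band std (percent).
#' @return `rd_curve`.
#' @export
rd_curve <- function(wavelengths, rd_mean, rd_std = NULL) {
  check_wavelength_axis(wavelengths)
  if (length(rd_mean) != length(wavelengths))
    stop("rd_mean length != wavelength count")
  if (any(rd_mean < 0)) stop("rd_mean must be non-negative")
  structure(list(wavelengths = wavelengths, rd_mean = rd_mean,
                 rd_std = rd_std %||% rep(0, length(rd_mean)),
                 average_rd_mean = mean(rd_mean), n_excluded = 0L),
            class = "rd_curve")
}

#' Operating-bandwidth cutoffs from an RD curve
#'
#' The initial cutoff is the first band, scanning from the low-wavelength
#' end, that starts a run of `run_length` consecutive bands with
#' `rd_mean <= average_rd_mean`; the final cutoff is found symmetrically
#' from the high-wavelength end. The run requirement stops a single quiet
#' band inside a noisy edge from being taken as the sensor's operating
#' limit. Scaling the curve by any positive constant leaves the cutoffs
#' unchanged (the threshold scales with it).
#'
#' @param curve `rd_curve`.
#' @param run_length required run of sub-threshold bands.
#' @return list of class `cutoff_result`: `initial_nm`, `final_nm`,
#'   `initial_idx`, `final_idx`, `curve`.
#' @export
find_cutoffs <- function(curve, run_length = 5L) {
  ok <- curve$rd_mean <= curve$average_rd_mean
  nb <- length(ok)
  run_length <- min(run_length, nb)
  runs_ok <- function(i) all(ok[i:(i + run_length - 1L)])
  init <- NA_integer_
  for (i in seq_len(nb - run_length + 1L))
    if (runs_ok(i)) { init <- i; break }
  if (is.na(init))
    stop("no run of ", run_length, " bands under the Average RD_mean; ",
         "sensor never reaches a stable operating region")
  fin <- NA_integer_
  for (i in seq(nb, run_length, by = -1L))
    if (all(ok[(i - run_length + 1L):i])) { fin <- i; break }
  if (fin <= init) stop("cutoff scan produced an empty operating bandwidth")
  structure(list(initial_idx = init, final_idx = fin,
                 initial_nm = curve$wavelengths[init],
                 final_nm = curve$wavelengths[fin],
                 curve = curve),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> bands %d-%d (%.1f-%.1f nm)\n",
              x$initial_idx, x$final_idx, x$initial_nm, x$final_nm))
  invisible(x)
}

#' Fixed cutoffs on a camera grid
#'
#' Builds a `cutoff_result` from configured wavelengths instead of an RD
#' analysis (nearest grid band at or inside each limit), for reproducing a
#' previously chosen operating bandwidth.
#'
#' @param wavelengths camera band grid (nm).
#' @param initial_nm,final_nm desired limits.
#' @return `cutoff_result` (with a degenerate zero curve).
#' @export
fixed_cutoffs <- function(wavelengths, initial_nm, final_nm) {
  if (initial_nm >= final_nm) stop("initial_nm must be < final_nm")
  init <- which(wavelengths >= initial_nm)[1]
  fin <- utils::tail(which(wavelengths <= final_nm), 1)
  if (is.na(init) || length(fin) == 0L || fin <= init)
    stop("cutoff range [", initial_nm, ", ", final_nm,
         "] selects no bands on this grid")
  structure(list(initial_idx = init, final_idx = fin,
                 initial_nm = wavelengths[init],
                 final_nm = wavelengths[fin],
                 curve = rd_curve(wavelengths,
                                  rep(0, length(wavelengths)))),
            class = "cutoff_result")
}

#' Bilinear spatial upsampling of a cube
#'
#' Each band is independently resampled to `target_dims` by bilinear
#' interpolation over the nearest 2x2 source neighbourhood, with the
#' corner-aligned coordinate mapping (the four corner pixels of the source
#' map exactly onto the four corners of the target). Used to raise the NIR
#' cube to the VNIR pixel size before registration.
#'
#' @param cube `hs_cube`.
#' @param target_dims `c(rows, cols)`, each at least the source dimension.
#' @return upsampled `hs_cube`.
#' @export
upsample_bilinear <- function(cube, target_dims) {
  d <- dim(cube$data)
  if (any(target_dims < d[1:2]))
    stop("target dimensions must be >= source (downsampling unsupported)")
  if (all(target_dims == d[1:2])) return(cube)
  src_x <- (seq_len(target_dims[2]) - 1) * (d[2] - 1) /
    (target_dims[2] - 1) + 1
  src_y <- (seq_len(target_dims[1]) - 1) * (d[1] - 1) /
    (target_dims[1] - 1) + 1
  gx <- rep(src_x, each = target_dims[1])
  gy <- rep(src_y, times = target_dims[2])
  out <- array(0, c(target_dims, d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- base::matrix(bilinear_sample(cube$data[, , b], gx, gy),
                               target_dims[1], target_dims[2])
  hs_cube(out, cube$wavelengths, cube$modality,
          c(cube$meta, list(upsampled_from = d[1:2])))
}

#' Transfer a label map onto a co-registered grid
#'
#' Copies categorical labels onto a grid of the requested dimensions using
#' nearest-neighbour sampling (corner-aligned), so no new label values are
#' ever introduced. With identical dimensions this is the identity.
#'
#' @param lm `label_map` (drawn on the fixed VNIR grid).
#' @param target_dims `c(rows, cols)` of the co-registered grid.
#' @return `label_map`.
#' @export
transfer_labels <- function(lm, target_dims) {
  d <- dim(lm$labels)
  if (all(target_dims == d)) return(lm)
  src_r <- round((seq_len(target_dims[1]) - 1) * (d[1] - 1) /
                 (target_dims[1] - 1) + 1)
  src_c <- round((seq_len(target_dims[2]) - 1) * (d[2] - 1) /
                 (target_dims[2] - 1) + 1)
  label_map(lm$labels[src_r, src_c, drop = FALSE], lm$class_names)
}

#' Reflectance offset between two spectral segments
#'
#' Additive level correction making the NIR segment continue the VNIR
#' segment: the mean of the last `k_bands` retained VNIR bands minus the
#' mean of the first `k_bands` retained NIR bands. Adding the offset to the
#' NIR segment levels the two sides of the junction.
#'
#' @param vnir_spectrum,nir_spectrum numeric vectors already cut to the
#'   operating bandwidth.
#' @param k_bands number of edge bands averaged on each side.
#' @return scalar offset to add to the NIR spectrum.
#' @export
reflectance_offset <- function(vnir_spectrum, nir_spectrum, k_bands = 5L) {
  if (k_bands < 1L || k_bands > length(vnir_spectrum) ||
      k_bands > length(nir_spectrum))
    stop("`k_bands` exceeds a segment length")
  mean(utils::tail(vnir_spectrum, k_bands)) -
    mean(utils::head(nir_spectrum, k_bands))
}

#' Fuse co-registered VNIR and NIR cubes into one wide-range cube
#'
#' Crops each cube to its operating bandwidth, levels each pixel's NIR
#' segment onto its VNIR segment with a per-pixel [reflectance_offset()],
#' concatenates the segments, and records the excluded wavelength gap
#' between the retained ranges. The gap is kept as metadata — no bands are
#' interpolated across it, preserving the NIR segment's original standard
#' deviation. By default the result is per-pixel min-max normalized.
#'
#' @param vnir,nir_registered `hs_cube`s on the same spatial grid (NIR
#'   already upsampled and registered).
#' @param vnir_cut,nir_cut `cutoff_result`s for the two cameras.
#' @param k_bands edge bands for the offset estimate.
#' @param normalize apply [minmax_normalize_pixels()] to the result.
#' @return list of class `fused_cube`: `cube` (`hs_cube`, modality FUSED),
#'   `segment_boundary` (index of the first NIR-origin band), `gap_nm`
#'   (`c(lo, hi)`), `offset_mean`, `offset_sd`.
#' @export
fuse <- function(vnir, nir_registered, vnir_cut, nir_cut, k_bands = 5L,
                 normalize = TRUE) {
  d <- dim(vnir$data)
  if (!all(d[1:2] == dim(nir_registered$data)[1:2]))
    stop("cubes must share spatial dimensions (register and upsample first)")
  vkeep <- vnir_cut$initial_idx:vnir_cut$final_idx
  nkeep <- nir_cut$initial_idx:nir_cut$final_idx
  wv <- vnir$wavelengths[vkeep]
  wn <- nir_registered$wavelengths[nkeep]
  if (utils::tail(wv, 1) >= wn[1])
    stop("retained ranges overlap (", utils::tail(wv, 1), " >= ", wn[1],
         " nm); the gap must be non-negative")
  npix <- d[1] * d[2]
  v_flat <- base::matrix(vnir$data[, , vkeep], npix, length(vkeep))
  n_flat <- base::matrix(nir_registered$data[, , nkeep], npix,
                         length(nkeep))
  k <- min(k_bands, length(vkeep), length(nkeep))
  off <- rowMeans(v_flat[, (length(vkeep) - k + 1L):length(vkeep),
                         drop = FALSE]) -
         rowMeans(n_flat[, seq_len(k), drop = FALSE])
  fused_flat <- cbind(v_flat, n_flat + off)
  cube <- hs_cube(array(fused_flat, c(d[1], d[2], length(vkeep) +
                                        length(nkeep))),
                  c(wv, wn), "FUSED",
                  meta = list(vnir_bands = length(vkeep),
                              nir_bands = length(nkeep),
                              gap_nm = c(utils::tail(wv, 1), wn[1])))
  if (normalize) cube <- minmax_normalize_pixels(cube)
  structure(list(cube = cube,
                 segment_boundary = length(vkeep) + 1L,
                 gap_nm = c(utils::tail(wv, 1), wn[1]),
                 offset_mean = mean(off), offset_sd = stats::sd(off)),
            class = "fused_cube")
}

#' @export
print.fused_cube <- function(x, ...) {
  cat(sprintf(
    "<fused_cube> %d + %d bands, gap %.1f-%.1f nm, mean offset %.4f\n",
    x$segment_boundary - 1L, n_bands(x$cube) - x$segment_boundary + 1L,
    x$gap_nm[1], x$gap_nm[2], x$offset_mean))
  invisible(x)
}

#' Write a fused cube as ENVI plus JSON sidecar
#' @param fc `fused_cube`.
#' @param path base path.
#' @return `path`, invisibly.
#' @export
write_fused <- function(fc, path) {
  write_envi(fc$cube, path)
  jsonlite::write_json(list(segment_boundary = fc$segment_boundary,
                            gap_nm = fc$gap_nm,
                            offset_mean = fc$offset_mean,
                            offset_sd = fc$offset_sd),
                       paste0(path, "_fusion.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
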