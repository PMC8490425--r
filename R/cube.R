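#' Hyperspectral cube
#'
#' An `hs_cube` bundles a 3-D reflectance array indexed `(row, col, band)`
#' with its wavelength axis (band centers, nm), a modality tag and free-form
#' provenance metadata. Reflectance is dimensionless and non-negative after
#' calibration.
#'
#' @param data numeric 3-D array, dimensions `(rows, cols, bands)`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param modality one of `"VNIR"`, `"NIR"`, `"FUSED"`.
#' @param meta named list of provenance entries (capture id, calibration
#'   state, generator truths, ...).
#' @return An object of class `hs_cube`.
#' @examples
#' cube <- hs_cube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(450, 550, 650))
#' dim(cube$data)
#' @export
hs_cube <- function(data, wavelengths, modality = "VNIR", meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows, cols, bands)")
  wavelengths <- as.numeric(wavelengths)
  check_wavelength_axis(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("band count (", dim(data)[3], ") != wavelength count (",
         length(wavelengths), ")")
  if (dim(data)[1] < 2L || dim(data)[2] < 2L)
    stop("spatial dimensions must be at least 2x2")
  modality <- match.arg(modality, c("VNIR", "NIR", "FUSED"))
  structure(list(data = data, wavelengths = wavelengths,
                 modality = modality, meta = meta),
            class = "hs_cube")
}

check_wavelength_axis <- function(w) {
  if (length(w) < 2L) stop("wavelength axis needs at least 2 bands")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("wavelengths must be finite and positive")
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing")
  invisible(w)
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hs_cube %s> %d x %d pixels, %d bands [%.1f-%.1f nm]\n",
              x$modality, d[1], d[2], d[3],
              x$wavelengths[1], x$wavelengths[length(x$wavelengths)]))
  invisible(x)
}

#' @export
dim.hs_cube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3]

#' Pixel-label map
#'
#' Integer class labels on an image grid: 0 marks unlabeled pixels, values
#' `1..C` index `class_names`.
#'
#' @param labels integer matrix (rows x cols).
#' @param class_names character vector of C class names.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, class_names) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0L)) stop("labels must be >= 0")
  if (max(labels) > length(class_names))
    stop("label value ", max(labels), " exceeds number of class names (",
         length(class_names), ")")
  structure(list(labels = labels, class_names = as.character(class_names)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes (%s), %d labeled pixels\n",
              nrow(x$labels), ncol(x$labels), length(x$class_names),
              paste(x$class_names, collapse = ", "), sum(x$labels > 0L)))
  invisible(x)
}

#' Reflectance calibration with white and dark references
#'
#' Converts raw sensor counts to reflectance using the standard white/dark
#' normalization `R = (raw - dark) / (white - dark)`, which removes the
#' illumination profile and the sensor dark current. Where the denominator is
#' degenerate (dead or saturated pixels, `white - dark <= eps`) it is floored
#' at `eps` and the result clipped, so isolated bad pixels cannot dominate
#' downstream similarity metrics.
#'
#' @param raw `hs_cube` of raw counts.
#' @param white,dark reference captures: `hs_cube`s on the same band grid as
#'   `raw`, or arrays of the same dimensions.
#' @param eps denominator floor.
#' @param clip_max reflectance ceiling; output clipped to `[0, clip_max]`.
#' @return Calibrated `hs_cube`; `meta$calibrated` is set to `TRUE` and
#'   `meta$n_degenerate` counts floored denominators.
#' @export
calibrate <- function(raw, white, dark, eps = 1e-6, clip_max = 2) {
  w <- if (inherits(white, "hs_cube")) white$data else white
  d <- if (inherits(dark, "hs_cube")) dark$data else dark
  if (!all(dim(w) == dim(raw$data)) || !all(dim(d) == dim(raw$data)))
    stop("white/dark references must match the raw cube dimensions")
  denom <- w - d
  if (mean(denom > 0) < 0.99)
    stop("white <= dark on more than 1% of elements; references look swapped")
  n_bad <- sum(denom <= eps)
  if (n_bad > 0L) {
    warning(n_bad, " degenerate white-dark elements floored at eps")
    denom[denom <= eps] <- eps
  }
  refl <- (raw$data - d) / denom
  refl[refl < 0] <- 0
  refl[refl > clip_max] <- clip_max
  meta <- raw$meta
  meta$calibrated <- TRUE
  meta$n_degenerate <- n_bad
  hs_cube(refl, raw$wavelengths, raw$modality, meta)
}

#' Smooth spectra along the band axis
#'
#' Moving-average filter applied independently to each pixel's spectrum;
#' spatial content is untouched. Band-edge output uses a shrinking window
#' (the kernel is renormalized over the in-range bands) so the filter is
#' mean-preserving on interior bands and never pads with zeros.
#'
#' @param cube `hs_cube`.
#' @param window odd integer window length; `1` is the identity.
#' @return Smoothed `hs_cube`.
#' @export
smooth_spectra <- function(cube, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1")
  if (window > n_bands(cube)) stop("`window` exceeds the band count")
  if (window == 1L) return(cube)
  d <- dim(cube$data)
  half <- (window - 1L) %/% 2L
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  # cumulative-sum moving average with edge renormalization
  cs <- cbind(0, t(apply(flat, 1L, cumsum)))
  lo <- pmax(seq_len(d[3]) - half, 1L)
  hi <- pmin(seq_len(d[3]) + half, d[3])
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(flat))
  out <- array(sm, d)
  hs_cube(out, cube$wavelengths, cube$modality,
          c(cube$meta, list(smoothed_window = window)))
}

#' Crop a cube to a wavelength range
#'
#' Retains bands whose center wavelength lies in the closed interval
#' `[lo_nm, hi_nm]`.
#'
#' @param cube `hs_cube`.
#' @param lo_nm,hi_nm inclusive wavelength limits in nm.
#' @return Cropped `hs_cube`.
#' @export
crop_bands <- function(cube, lo_nm, hi_nm) {
  if (lo_nm >= hi_nm) stop("`lo_nm` must be < `hi_nm`")
  keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
  if (length(keep) < 2L)
    stop("fewer than 2 bands in [", lo_nm, ", ", hi_nm, "] nm")
  hs_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
          cube$modality, cube$meta)
}

#' Pseudo-RGB rendering of a cube
#'
#' Maps three bands to the R, G and B channels and min-max scales each
#' channel to `[0, 1]`. VNIR defaults pick the bands nearest 708, 539 and
#' 470 nm; for NIR (or any cube whose range misses the visible) a single
#' mid-range band is replicated, giving the false-color grayscale rendering
#' typical of NIR sensors.
#'
#' @param cube `hs_cube` with at least 3 bands.
#' @param bands_nm length-3 numeric of target wavelengths for R, G, B, or
#'   `NULL` for the modality default.
#' @return `rows x cols x 3` array in `[0, 1]`.
#' @export
pseudo_rgb <- function(cube, bands_nm = NULL) {
  if (n_bands(cube) < 3L) stop("pseudo-RGB needs at least 3 bands")
  w <- cube$wavelengths
  if (is.null(bands_nm)) {
    visible <- c(708, 539, 470)
    if (cube$modality == "VNIR" || all(visible >= min(w) & visible <= max(w))) {
      bands_nm <- visible
    } else {
      bands_nm <- rep(w[ceiling(length(w) / 2)], 3L)
    }
  }
  idx <- vapply(bands_nm, function(t) which.min(abs(w - t)), integer(1))
  out <- array(0, c(dim(cube$data)[1:2], 3L))
  for (k in 1:3) {
    plane <- cube$data[, , idx[k]]
    rng <- range(plane)
    out[, , k] <- if (rng[2] > rng[1]) (plane - rng[1]) / (rng[2] - rng[1])
                  else plane * 0 + 0.5
  }
  out
}

#' Convert an RGB image to grayscale
#'
#' Rec. 601 luminance weights (0.299, 0.587, 0.114); deterministic and
#' idempotent on already-gray input.
#'
#' @param rgb `rows x cols x 3` array.
#' @return matrix in `[0, 1]`.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be a rows x cols x 3 array")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Per-pixel min-max normalization of spectra
#'
#' Rescales every pixel's spectrum to `[0, 1]`
#' (`s' = (s - min s) / (max s - min s)`), homogenizing reflectance levels
#' across pixels before segmentation or classification. Pixels with a
#' constant spectrum are mapped to all zeros and counted in
#' `meta$n_constant_pixels`.
#'
#' @param cube `hs_cube`.
#' @return Normalized `hs_cube`.
#' @export
minmax_normalize_pixels <- function(cube) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  mins <- do.call(pmin, as.data.frame(flat))
  maxs <- do.call(pmax, as.data.frame(flat))
  rng <- maxs - mins
  const <- rng <= 0
  if (any(const)) {
    warning(sum(const), " constant-spectrum pixels mapped to zeros")
    rng[const] <- 1
  }
  flat <- (flat - mins) / rng
  flat[const, ] <- 0
  meta <- cube$meta
  meta$normalized <- TRUE
  meta$n_constant_pixels <- sum(const)
  hs_cube(array(flat, d), cube$wavelengths, cube$modality, meta)
}
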