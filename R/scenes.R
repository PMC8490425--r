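#' Specification of a synthetic dual-camera scene
#'
#' Describes the two sensor grids, spatial dimensions, the true NIR-to-VNIR
#' transform, and the band-dependent noise model used by all scene
#' generators. The noise standard deviation is flat over the interior of
#' each camera's range and amplified over the first/last `edge_frac`
#' fraction of bands, emulating the poor signal-to-noise of push-broom
#' sensors at their spectral extremes.
#'
#' Sizes: `"test"` (default) uses 120 VNIR / 60 NIR bands and small spatial
#' dims so a full pipeline runs in seconds; `"full"` matches a realistic
#' two-camera rig (826 VNIR bands over 400-1000 nm at 939 x 743 pixels, 172
#' NIR bands over 900-1700 nm at 320 x 253 pixels).
#'
#' @param size `"test"` or `"full"` preset.
#' @param vnir_wavelengths,nir_wavelengths numeric band-center grids (nm).
#' @param vnir_dims,nir_dims `c(rows, cols)` per camera.
#' @param true_transform `transform_model` mapping NIR to VNIR frame, or
#'   `NULL` for the generator default.
#' @param base_sd interior per-band noise standard deviation (reflectance
#'   units).
#' @param edge_frac fraction of bands at each spectral extreme with
#'   amplified noise.
#' @param edge_gain multiplicative amplification at the extremes (sd is
#'   `base_sd * (1 + edge_gain)` there).
#' @param seed integer generator seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(size = c("test", "full"),
                       vnir_wavelengths = NULL, nir_wavelengths = NULL,
                       vnir_dims = NULL, nir_dims = NULL,
                       true_transform = NULL,
                       base_sd = 0.01, edge_frac = 0.1, edge_gain = 9,
                       seed = 1L) {
  size <- match.arg(size)
  if (is.null(vnir_wavelengths))
    vnir_wavelengths <- if (size == "test") seq(400, 1000, length.out = 120)
                        else seq(400, 1000, length.out = 826)
  if (is.null(nir_wavelengths))
    nir_wavelengths <- if (size == "test") seq(900, 1700, length.out = 60)
                       else seq(900, 1700, length.out = 172)
  if (is.null(vnir_dims)) vnir_dims <- if (size == "test") c(96L, 96L)
                                       else c(939L, 743L)
  if (is.null(nir_dims)) nir_dims <- if (size == "test") c(48L, 48L)
                                     else c(320L, 253L)
  check_wavelength_axis(vnir_wavelengths)
  check_wavelength_axis(nir_wavelengths)
  if (any(vnir_dims < 8L) || any(nir_dims < 8L))
    stop("scene dimensions must be at least 8x8")
  if (base_sd < 0 || edge_gain < 0 || edge_frac < 0 || edge_frac >= 0.5)
    stop("invalid noise profile")
  structure(list(vnir_wavelengths = vnir_wavelengths,
                 nir_wavelengths = nir_wavelengths,
                 vnir_dims = as.integer(vnir_dims),
                 nir_dims = as.integer(nir_dims),
                 true_transform = true_transform,
                 base_sd = base_sd, edge_frac = edge_frac,
                 edge_gain = edge_gain, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Per-band noise standard deviations for a sensor
#' @param spec `scene_spec`.
#' @param camera `"vnir"` or `"nir"`.
#' @return numeric vector, one sd per band.
#' @export
noise_profile <- function(spec, camera = c("vnir", "nir")) {
  camera <- match.arg(camera)
  nb <- length(spec[[paste0(camera, "_wavelengths")]])
  n_edge <- floor(spec$edge_frac * nb)
  sd <- rep(spec$base_sd, nb)
  if (n_edge > 0) {
    idx <- c(seq_len(n_edge), seq(nb - n_edge + 1L, nb))
    sd[idx] <- spec$base_sd * (1 + spec$edge_gain)
  }
  sd
}

# clean-band index range implied by the noise profile (generator truth)
true_cutoff_idx <- function(spec, camera) {
  nb <- length(spec[[paste0(camera, "_wavelengths")]])
  n_edge <- floor(spec$edge_frac * nb)
  c(n_edge + 1L, nb - n_edge)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a sensor capture of an ideal cube
#'
#' Adds independent zero-mean Gaussian noise with per-band standard
#' deviation from the profile, then clips at zero (sensors do not report
#' negative reflectance).
#'
#' @param ideal `hs_cube` of true reflectance.
#' @param sd_per_band numeric vector, one noise sd per band.
#' @param seed integer seed; identical inputs give bit-identical captures.
#' @return noisy `hs_cube`.
#' @export
sensor_capture <- function(ideal, sd_per_band, seed) {
  d <- dim(ideal$data)
  if (length(sd_per_band) != d[3])
    stop("noise profile length != band count")
  out <- with_seed(seed, {
    noise <- array(stats::rnorm(prod(d)), d)
    sweep(noise, 3L, sd_per_band, "*")
  })
  res <- ideal$data + out
  res[res < 0] <- 0
  hs_cube(res, ideal$wavelengths, ideal$modality,
          c(ideal$meta, list(capture_seed = as.integer(seed))))
}

new_scene_pair <- function(...) structure(list(...), class = "scene_pair")

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair %s> VNIR %s, NIR %s\n",
              x$meta$kind %||% "?",
              paste(dim(x$vnir$data), collapse = "x"),
              paste(dim(x$nir$data), collapse = "x")))
  invisible(x)
}

#' Synthetic flat-reflectance reference panel, captured twice
#'
#' Emulates repeat captures of a certified flat reflectance standard (e.g.
#' a sintered PTFE panel): spatially uniform true reflectance on both
#' camera grids, pushed twice through the band-dependent sensor noise
#' model. The repeat pair is the input the RD band-trimming procedure
#' needs; the clean-band truth implied by the noise profile is recorded in
#' `meta` for parameter-recovery checks.
#'
#' @param spec `scene_spec`.
#' @param reflectance true panel reflectance.
#' @return `scene_pair` with `vnir`, `nir`, `vnir_repeat`, `nir_repeat`
#'   and `meta$vnir_cut_idx`, `meta$nir_cut_idx` (first/last clean band).
#' @export
make_reference_panel <- function(spec, reflectance = 0.95) {
  ideal <- function(dims, w, mod)
    hs_cube(array(reflectance, c(dims, length(w))), w, mod)
  iv <- ideal(spec$vnir_dims, spec$vnir_wavelengths, "VNIR")
  ni <- ideal(spec$nir_dims, spec$nir_wavelengths, "NIR")
  sv <- noise_profile(spec, "vnir"); sn <- noise_profile(spec, "nir")
  new_scene_pair(
    vnir = sensor_capture(iv, sv, spec$seed),
    nir = sensor_capture(ni, sn, spec$seed + 1L),
    vnir_repeat = sensor_capture(iv, sv, spec$seed + 2L),
    nir_repeat = sensor_capture(ni, sn, spec$seed + 3L),
    true_transform = NULL,
    meta = list(kind = "reference_panel", seed = spec$seed,
                reflectance = reflectance,
                vnir_cut_idx = true_cutoff_idx(spec, "vnir"),
                nir_cut_idx = true_cutoff_idx(spec, "nir")))
}

#' Random projective perturbation of the identity
#'
#' Samples a plausible misalignment for a near-perpendicular two-camera
#' rig: rotation up to `max_rot_deg`, isotropic scale in `scale_range`,
#' translation up to `max_shift_px`, and mild perspective tilt, composed
#' about the image center.
#'
#' @param dims `c(rows, cols)` of the frame the transform acts on.
#' @param seed integer seed.
#' @param max_rot_deg,scale_range,max_shift_px,max_tilt perturbation
#'   bounds.
#' @return projective `transform_model`.
#' @export
random_projective <- function(dims, seed, max_rot_deg = 5,
                              scale_range = c(0.9, 1.1), max_shift_px = 6,
                              max_tilt = 5e-4) {
  with_seed(seed, {
    th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
    s <- stats::runif(1, scale_range[1], scale_range[2])
    tx <- stats::runif(1, -max_shift_px, max_shift_px)
    ty <- stats::runif(1, -max_shift_px, max_shift_px)
    g <- stats::runif(1, -max_tilt, max_tilt)
    h <- stats::runif(1, -max_tilt, max_tilt)
    cx <- (dims[2] + 1) / 2; cy <- (dims[1] + 1) / 2
    core <- rbind(c(s * cos(th), -s * sin(th), tx),
                  c(s * sin(th),  s * cos(th), ty),
                  c(g, h, 1))
    to_ctr <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
    from_ctr <- rbind(c(1, 0, cx), c(0, 1, cy), c(0, 0, 1))
    transform_model("projective", from_ctr %*% core %*% to_ctr)
  })
}

# continuous registration pattern: checkerboard with per-cell random albedo
# plus random disks; returns closure (x, y) -> albedo in [0, 1]
make_pattern_fun <- function(dims, seed, cell = 16, n_disks = 12) {
  with_seed(seed, {
    ncr <- ceiling(dims[1] / cell) + 2L
    ncc <- ceiling(dims[2] / cell) + 2L
    albedo <- base::matrix(stats::runif(ncr * ncc, 0.05, 0.95), ncr, ncc)
    dx <- stats::runif(n_disks, 0.1 * dims[2], 0.9 * dims[2])
    dy <- stats::runif(n_disks, 0.1 * dims[1], 0.9 * dims[1])
    dr <- stats::runif(n_disks, 3, 7)
    dv <- stats::runif(n_disks, 0, 1)
    function(x, y) {
      ci <- pmin(pmax(floor(y / cell) + 2L, 1L), ncr)
      cj <- pmin(pmax(floor(x / cell) + 2L, 1L), ncc)
      val <- albedo[cbind(ci, cj)]
      for (k in seq_len(n_disks)) {
        inside <- (x - dx[k])^2 + (y - dy[k])^2 < dr[k]^2
        val[inside] <- dv[k]
      }
      val
    }
  })
}

# render a pattern closure on an integer grid with nxn supersampling
render_pattern <- function(pattern, dims, transform = NULL, ss = 3L) {
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- base::matrix(0, dims[1], dims[2])
  gx <- rep(seq_len(dims[2]), each = dims[1])
  gy <- rep(seq_len(dims[1]), times = dims[2])
  for (ox in offs) for (oy in offs) {
    px <- gx + ox; py <- gy + oy
    if (!is.null(transform)) {
      mapped <- apply_transform(transform, cbind(px, py))
      px <- mapped[, 1]; py <- mapped[, 2]
    }
    acc <- acc + base::matrix(pattern(px, py), dims[1], dims[2])
  }
  acc / ss^2
}

#' Synthetic registration target with known projective misalignment
#'
#' A high-contrast pattern (checkerboard with random cell albedos plus
#' disks) rendered in the VNIR frame, and the same continuous pattern
#' re-rendered in the NIR frame through the true NIR-to-VNIR transform.
#' Both renders evaluate the analytic pattern (with supersampled area
#' sampling), so the stored transform reproduces the geometry exactly and
#' control-point recovery can be judged at subpixel precision. Foreground
#' and background carry distinct smooth spectral signatures spanning both
#' camera ranges. The NIR cube is rendered on the VNIR-sized grid, i.e. in
#' the post-upsampling frame in which registration is performed.
#'
#' @param spec `scene_spec`; `spec$true_transform` is used when set,
#'   otherwise a [random_projective()] perturbation is drawn from
#'   `spec$seed`.
#' @return `scene_pair`; `meta$control_points` holds a grid of NIR-frame
#'   points with their true VNIR-frame positions.
#' @export
make_registration_target <- function(spec) {
  dims <- spec$vnir_dims
  tt <- spec$true_transform %||%
    random_projective(dims, spec$seed + 17L)
  pattern <- make_pattern_fun(dims, spec$seed + 29L)
  vnir_alb <- render_pattern(pattern, dims)
  nir_alb <- render_pattern(pattern, dims, transform = tt)
  # does any of the NIR frame see the pattern?
  ctr <- apply_transform(tt, cbind(rep(seq(8, dims[2] - 8, length.out = 5),
                                       5),
                                   rep(seq(8, dims[1] - 8, length.out = 5),
                                       each = 5)))
  inside <- ctr[, 1] >= 1 & ctr[, 1] <= dims[2] &
            ctr[, 2] >= 1 & ctr[, 2] <= dims[1]
  if (!any(inside))
    stop("true transform maps the pattern fully outside the NIR frame")
  fore <- function(w) 0.25 + 0.6 * exp(-((w - 800) / 500)^2)
  back <- function(w) 0.85 - 0.5 * exp(-((w - 1200) / 600)^2)
  spectral_cube <- function(alb, w, mod) {
    nb <- length(w)
    dat <- outer(alb, fore(w)) + outer(1 - alb, back(w))
    hs_cube(array(dat, c(dim(alb), nb)), w, mod)
  }
  iv <- spectral_cube(vnir_alb, spec$vnir_wavelengths, "VNIR")
  ni <- spectral_cube(nir_alb, spec$nir_wavelengths, "NIR")
  cp_m <- cbind(rep(seq(12, dims[2] - 12, length.out = 5), 5),
                rep(seq(12, dims[1] - 12, length.out = 5), each = 5))
  new_scene_pair(
    vnir = sensor_capture(iv, noise_profile(spec, "vnir"), spec$seed),
    nir = sensor_capture(ni, noise_profile(spec, "nir"), spec$seed + 1L),
    true_transform = tt,
    meta = list(kind = "registration_target", seed = spec$seed,
                control_points = list(nir = cp_m,
                                      vnir = apply_transform(tt, cp_m)),
                vnir_cut_idx = true_cutoff_idx(spec, "vnir"),
                nir_cut_idx = true_cutoff_idx(spec, "nir")))
}

#' Synthetic plastic-like scene with color and material structure
#'
#' Places non-overlapping shaped regions on the canvas and assigns each a
#' (color, material) combination. A region's reflectance is a shared base
#' level plus a color component (a distinct visible-range bump, zero above
#' 900 nm) plus a material component (a distinct absorption dip, confined
#' above 956 nm). Combinations cycle through the full material x color
#' product, so whenever more than one color shares a material (and vice
#' versa) the material-color problem is unsolvable from either camera
#' alone — the construction behind comparing modalities. Three ground
#' truths (color, material, material-color) are produced on the VNIR grid.
#'
#' The NIR frame views the same canvas through the true transform (default:
#' the corner-aligned scaling from the NIR grid onto the VNIR canvas, the
#' geometry of a co-aligned lower-resolution sensor).
#'
#' @param spec `scene_spec`.
#' @param n_objects number of regions (>= 2).
#' @param materials,colors character vectors of class names (each >= 2).
#' @return `scene_pair` with `vnir`, `nir`, label maps `color_gt`,
#'   `material_gt`, `material_color_gt`, and `vnir_labels` (the
#'   material-color map, the scene's manual-labeling analogue).
#' @export
make_plastic_scene <- function(spec, n_objects = 6L,
                               materials = c("ABS", "PLA"),
                               colors = c("red", "green", "blue")) {
  if (n_objects < 1L) stop("need at least one object")
  if (length(materials) < 2L || length(colors) < 2L)
    stop("need at least 2 materials and 2 colors")
  dims <- spec$vnir_dims
  grid_n <- ceiling(sqrt(n_objects))
  cell_r <- dims[1] / grid_n; cell_c <- dims[2] / grid_n
  if (min(cell_r, cell_c) < 8)
    stop("too many objects for the canvas")
  combos <- expand.grid(material = seq_along(materials),
                        color = seq_along(colors))
  combos <- combos[((seq_len(n_objects) - 1L) %% nrow(combos)) + 1L, ]
  color_lab <- base::matrix(0L, dims[1], dims[2])
  mat_lab <- base::matrix(0L, dims[1], dims[2])
  shape <- with_seed(spec$seed + 7L,
                     sample(c("rect", "disk"), n_objects, replace = TRUE))
  for (k in seq_len(n_objects)) {
    gi <- (k - 1L) %/% grid_n; gj <- (k - 1L) %% grid_n
    r0 <- gi * cell_r; c0 <- gj * cell_c
    rr <- round(r0 + 0.2 * cell_r):round(r0 + 0.8 * cell_r)
    cc <- round(c0 + 0.2 * cell_c):round(c0 + 0.8 * cell_c)
    rr <- rr[rr >= 1 & rr <= dims[1]]; cc <- cc[cc >= 1 & cc <= dims[2]]
    if (shape[k] == "rect") {
      color_lab[rr, cc] <- combos$color[k]
      mat_lab[rr, cc] <- combos$material[k]
    } else {
      cy <- mean(rr); cx <- mean(cc); rad <- min(diff(range(rr)),
                                                 diff(range(cc))) / 2
      for (r in rr) {
        sel <- cc[(cx - cc)^2 + (cy - r)^2 <= rad^2]
        color_lab[r, sel] <- combos$color[k]
        mat_lab[r, sel] <- combos$material[k]
      }
    }
  }
  present <- sort(unique(1000L * mat_lab[mat_lab > 0] +
                         color_lab[mat_lab > 0]))
  mc_lab <- base::matrix(0L, dims[1], dims[2])
  lab_names <- character(length(present))
  for (i in seq_along(present)) {
    m <- present[i] %/% 1000L; cl <- present[i] %% 1000L
    mc_lab[mat_lab == m & color_lab == cl] <- i
    lab_names[i] <- paste(materials[m], colors[cl], sep = "-")
  }
  # spectral model: shared base level, a visible-range pigment bump per
  # color (zero above 900 nm) and a NIR absorption dip per material
  # (confined above 956 nm). Pigment concentration and hue vary from pixel
  # to pixel (mottling), so classes have realistic intra-class spread.
  color_centers <- seq(480, 480 + 70 * (length(colors) - 1),
                       length.out = length(colors))
  mat_centers <- seq(1050, 1550, length.out = length(materials))
  npix_v <- dims[1] * dims[2]
  jit <- with_seed(spec$seed + 41L, list(
    c_center = base::matrix(stats::rnorm(npix_v, 0, 20), dims[1], dims[2]),
    c_amp = base::matrix(1 + 0.2 * stats::rnorm(npix_v), dims[1], dims[2]),
    m_center = base::matrix(stats::rnorm(npix_v, 0, 40), dims[1], dims[2]),
    m_amp = base::matrix(1 + 0.2 * stats::rnorm(npix_v), dims[1],
                         dims[2])))
  build_ideal <- function(w, mod, m_lab, c_lab, jit_idx) {
    nb <- length(w)
    n <- length(m_lab)
    flat <- base::matrix(0.5, n, nb)
    cl <- as.vector(c_lab); ml <- as.vector(m_lab)
    cc <- color_centers[ifelse(cl > 0L, cl, 1L)] + jit$c_center[jit_idx]
    ca <- 0.35 * pmax(jit$c_amp[jit_idx], 0.2)
    mc <- mat_centers[ifelse(ml > 0L, ml, 1L)] + jit$m_center[jit_idx]
    ma <- 0.3 * pmax(jit$m_amp[jit_idx], 0.2)
    vis <- w < 900; nirb <- w > 956
    if (any(vis)) {
      wv <- w[vis]
      bump <- ca * exp(-(outer(cc, wv, "-") / 45)^2)
      bump[cl == 0L, ] <- 0
      flat[, vis] <- flat[, vis] + bump
    }
    if (any(nirb)) {
      wn <- w[nirb]
      dip <- ma * exp(-(outer(mc, wn, "-") / 70)^2)
      dip[ml == 0L, ] <- 0
      flat[, nirb] <- flat[, nirb] - dip
    }
    hs_cube(array(flat, c(dim(m_lab), nb)), w, mod)
  }
  idx_v <- seq_len(npix_v)
  iv <- build_ideal(spec$vnir_wavelengths, "VNIR", mat_lab, color_lab,
                    idx_v)
  # NIR frame: the same physical canvas (labels and mottling fields)
  # sampled through the true transform
  tt <- spec$true_transform %||% nir_to_vnir_scaling(spec)
  nd <- spec$nir_dims
  gx <- rep(seq_len(nd[2]), each = nd[1])
  gy <- rep(seq_len(nd[1]), times = nd[2])
  mapped <- apply_transform(tt, cbind(gx, gy))
  mr <- pmin(pmax(round(mapped[, 2]), 1L), dims[1])
  mc_ <- pmin(pmax(round(mapped[, 1]), 1L), dims[2])
  idx <- cbind(mr, mc_)
  mat_n <- base::matrix(mat_lab[idx], nd[1], nd[2])
  col_n <- base::matrix(color_lab[idx], nd[1], nd[2])
  ni <- build_ideal(spec$nir_wavelengths, "NIR", mat_n, col_n,
                    (mc_ - 1L) * dims[1] + mr)
  mc_names <- lab_names
  new_scene_pair(
    vnir = sensor_capture(iv, noise_profile(spec, "vnir"), spec$seed),
    nir = sensor_capture(ni, noise_profile(spec, "nir"), spec$seed + 1L),
    true_transform = tt,
    color_gt = label_map(color_lab, colors),
    material_gt = label_map(mat_lab, materials),
    material_color_gt = label_map(mc_lab, mc_names),
    vnir_labels = label_map(mc_lab, mc_names),
    meta = list(kind = "plastic_scene", seed = spec$seed,
                n_objects = n_objects,
                vnir_cut_idx = true_cutoff_idx(spec, "vnir"),
                nir_cut_idx = true_cutoff_idx(spec, "nir")))
}

# corner-aligned scaling from the NIR grid onto the VNIR canvas
nir_to_vnir_scaling <- function(spec) {
  sx <- (spec$vnir_dims[2] - 1) / (spec$nir_dims[2] - 1)
  sy <- (spec$vnir_dims[1] - 1) / (spec$nir_dims[1] - 1)
  transform_model("affine", rbind(c(sx, 0, 1 - sx), c(0, sy, 1 - sy),
                                  c(0, 0, 1)))
}

#' Write a scene pair to disk
#'
#' Emits ENVI cubes, PNG+JSON label maps and a JSON manifest recording the
#' seed, the true transform and the generator truths.
#'
#' @param scene `scene_pair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_pair <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_envi(scene$vnir, file.path(dir, "vnir"))
  write_envi(scene$nir, file.path(dir, "nir"))
  if (!is.null(scene$vnir_repeat)) {
    write_envi(scene$vnir_repeat, file.path(dir, "vnir_repeat"))
    write_envi(scene$nir_repeat, file.path(dir, "nir_repeat"))
  }
  for (nm in c("color_gt", "material_gt", "material_color_gt"))
    if (!is.null(scene[[nm]]))
      write_label_map(scene[[nm]], file.path(dir, nm))
  manifest <- list(
    kind = scene$meta$kind, seed = scene$meta$seed,
    true_transform = if (!is.null(scene$true_transform))
      as.vector(t(scene$true_transform$matrix)) else NULL,
    vnir_cut_idx = scene$meta$vnir_cut_idx,
    nir_cut_idx = scene$meta$nir_cut_idx)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
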