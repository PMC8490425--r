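#' Pipeline configuration
#'
#' Declarative description of a full fusion run, round-trippable through
#' YAML. Every stage that consumes randomness carries an explicit seed.
#'
#' @param scene scene source: a list with `kind`
#'   (`"plastic"`, `"registration_target"`, `"reference_panel"`), `size`
#'   (`"test"`/`"full"`), `seed`, and generator arguments; or `kind =
#'   "envi"` with `vnir`/`nir` base paths of calibrated cubes.
#' @param smoothing_window spectral smoothing window (odd; 1 disables).
#' @param registration list: `technique` (`"features"`, `"intensity"` or
#'   `"true"` to use the generator truth), `detector`, `kind`, `seed`,
#'   `trials`.
#' @param fusion list: `cutoff_mode` (`"auto"` = RD analysis of a matching
#'   reference panel, `"fixed"` = explicit nm limits, `"truth"` = generator
#'   clean-band truth), `k_bands`, `run_length`, and for `"fixed"`:
#'   `vnir_range`, `nir_range` (each `c(lo, hi)` nm).
#' @param evaluation `NULL`, or a list with `problems` and `classifier`
#'   for a modality comparison on plastic scenes.
#' @param output_dir artifact directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = list(kind = "plastic", size = "test",
                                         seed = 1L),
                            smoothing_window = 5L,
                            registration = list(technique = "features",
                                                detector = "blob",
                                                kind = "projective",
                                                seed = 1L, trials = 500L),
                            fusion = list(cutoff_mode = "truth",
                                          k_bands = 5L, run_length = 5L),
                            evaluation = NULL,
                            output_dir = tempfile("hsifuse_run_")) {
  structure(list(scene = scene, smoothing_window = smoothing_window,
                 registration = registration, fusion = fusion,
                 evaluation = evaluation, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param cfg `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full fusion pipeline
#'
#' Executes the processing chain — scene acquisition or generation,
#' spectral smoothing, NIR upsampling to the VNIR pixel size, spatial
#' registration (VNIR fixed, NIR moving), common-ROI cropping, operating
#' bandwidth selection and spectral fusion — writing artifacts and a JSON
#' manifest (config hash, seeds, per-stage similarity metrics) to
#' `cfg$output_dir`. Any stage failure halts with an error naming the
#' stage; artifacts of completed stages remain on disk.
#'
#' @param cfg `pipeline_config`.
#' @return list with `fused` (`fused_cube`), `transform`, `metrics`,
#'   `manifest_path`, invisibly also written to disk.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scene <- stage("scene", load_or_generate_scene(cfg$scene))
  vnir <- scene$vnir; nir <- scene$nir
  if (cfg$smoothing_window > 1L) {
    vnir <- stage("smoothing", smooth_spectra(vnir, cfg$smoothing_window))
    nir <- stage("smoothing", smooth_spectra(nir, cfg$smoothing_window))
  }
  vd <- dim(vnir$data)[1:2]
  reg <- cfg$registration
  fixed_gray <- gray_from_cube(vnir)
  if (identical(reg$technique, "true")) {
    if (is.null(scene$true_transform))
      stop("pipeline stage 'registration' failed: no generator truth")
    tm <- scene$true_transform
    warped <- stage("registration", warp_cube(nir, tm, vd))
  } else {
    nir_up <- stage("upsampling", {
      if (all(dim(nir$data)[1:2] == vd)) nir
      else upsample_bilinear(nir, vd)
    })
    moving_gray <- gray_from_cube(nir_up)
    tm <- stage("registration", {
      if (identical(reg$technique, "intensity"))
        register_intensity(fixed_gray, moving_gray,
                           kind = reg$kind %||% "affine")
      else
        register_features(fixed_gray, moving_gray,
                          detector = reg$detector %||% "blob",
                          kind = reg$kind %||% "projective",
                          seed = reg$seed %||% 1L,
                          trials = reg$trials %||% 500L)
    })
    warped <- stage("registration", warp_cube(nir_up, tm, vd))
  }
  roi <- stage("roi_crop", crop_common_roi(vnir, warped$cube,
                                           warped$mask))
  metrics <- stage("metrics", {
    f <- gray_from_cube(roi$fixed); m <- gray_from_cube(roi$warped)
    unreg <- gray_from_cube(if (exists("nir_up", inherits = FALSE))
      nir_up else warped$cube)
    list(ssim_after = ssim(f, m), mi_after = mutual_information(f, m),
         pcc_after = pcc(f, m),
         ssim_before = ssim(fixed_gray, unreg))
  })
  fus <- cfg$fusion
  cuts <- stage("cutoffs", switch(fus$cutoff_mode,
    fixed = list(
      vnir = fixed_cutoffs(vnir$wavelengths, fus$vnir_range[1],
                           fus$vnir_range[2]),
      nir = fixed_cutoffs(nir$wavelengths, fus$nir_range[1],
                          fus$nir_range[2])),
    truth = list(
      vnir = fixed_cutoffs(vnir$wavelengths,
                           vnir$wavelengths[scene$meta$vnir_cut_idx[1]],
                           vnir$wavelengths[scene$meta$vnir_cut_idx[2]]),
      nir = fixed_cutoffs(nir$wavelengths,
                          nir$wavelengths[scene$meta$nir_cut_idx[1]],
                          nir$wavelengths[scene$meta$nir_cut_idx[2]])),
    auto = {
      spec <- do.call(scene_spec, scene_spec_args(cfg$scene))
      panel <- make_reference_panel(spec)
      list(vnir = find_cutoffs(relative_difference(panel$vnir,
                                                   panel$vnir_repeat),
                               fus$run_length %||% 5L),
           nir = find_cutoffs(relative_difference(panel$nir,
                                                  panel$nir_repeat),
                              fus$run_length %||% 5L))
    },
    stop("unknown cutoff_mode: ", fus$cutoff_mode)))
  fused <- stage("fusion", fuse(roi$fixed, roi$warped, cuts$vnir,
                                cuts$nir, k_bands = fus$k_bands %||% 5L))
  write_fused(fused, file.path(cfg$output_dir, "fused"))
  if (inherits(tm, "transform_model"))
    write_transform(tm, file.path(cfg$output_dir, "transform.json"))
  report <- NULL
  if (!is.null(cfg$evaluation) &&
      identical(cfg$scene$kind %||% "plastic", "plastic")) {
    report <- stage("evaluation",
      compare_modalities(list(scene),
                         problems = cfg$evaluation$problems %||%
                           c("color", "material", "material_color"),
                         classifier = cfg$evaluation$classifier %||% "knn",
                         seed = cfg$scene$seed %||% 1L))
    write_eval_report(report, file.path(cfg$output_dir, "evaluation"))
  }
  manifest <- list(
    config = unclass(cfg), config_hash = config_hash(cfg),
    stages = c("scene", "smoothing", "upsampling", "registration",
               "roi_crop", "cutoffs", "fusion"),
    metrics = metrics,
    cutoffs = list(vnir = c(cuts$vnir$initial_nm, cuts$vnir$final_nm),
                   nir = c(cuts$nir$initial_nm, cuts$nir$final_nm)),
    gap_nm = fused$gap_nm,
    fused_bands = n_bands(fused$cube))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fused = fused, transform = tm, metrics = metrics,
                 report = report, manifest_path = manifest_path))
}

scene_spec_args <- function(scene_cfg) {
  keep <- intersect(names(scene_cfg),
                    names(formals(scene_spec)))
  scene_cfg[keep]
}

load_or_generate_scene <- function(scene_cfg) {
  kind <- scene_cfg$kind %||% "plastic"
  if (kind == "envi") {
    return(new_scene_pair(
      vnir = read_envi(scene_cfg$vnir, modality = "VNIR"),
      nir = read_envi(scene_cfg$nir, modality = "NIR"),
      true_transform = NULL,
      meta = list(kind = "envi")))
  }
  spec <- do.call(scene_spec, scene_spec_args(scene_cfg))
  switch(kind,
    plastic = do.call(make_plastic_scene,
                      c(list(spec = spec),
                        scene_cfg[intersect(names(scene_cfg),
                                            c("n_objects", "materials",
                                              "colors"))])),
    registration_target = make_registration_target(spec),
    reference_panel = make_reference_panel(spec),
    stop("unknown scene kind: ", kind))
}

#' Generate and write scene fixtures
#'
#' Wraps the scene generators: produces `n` seeded scenes of the requested
#' kind and writes each (cubes, label maps, manifest with truths) under
#' `dir`.
#'
#' @param kind `"plastic"`, `"registration_target"` or
#'   `"reference_panel"`.
#' @param n number of scenes.
#' @param dir output directory.
#' @param seed base seed; scene i uses `seed + i - 1`.
#' @param size scene size preset.
#' @param ... forwarded to the generator.
#' @return character vector of scene directories.
#' @export
simulate_scenes <- function(kind, n = 1L, dir = tempfile("hsifuse_sim_"),
                            seed = 1L, size = "test", ...) {
  out <- character(n)
  for (i in seq_len(n)) {
    spec <- scene_spec(size = size, seed = as.integer(seed + i - 1L))
    scene <- switch(kind,
      plastic = make_plastic_scene(spec, ...),
      registration_target = make_registration_target(spec),
      reference_panel = make_reference_panel(spec),
      stop("unknown scene kind: ", kind))
    out[i] <- file.path(dir, sprintf("%s_%03d", kind, i))
    write_scene_pair(scene, out[i])
  }
  out
}
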