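# hsifuse

Registration and spectral fusion of dual-camera hyperspectral images in R.

Broadband hyperspectral imaging of biological tissue needs two sensors: a
silicon (CCD/CMOS) camera for the visible and near-infrared range (VNIR,
~400–1000 nm) and an InGaAs camera for the near-infrared (NIR,
~900–1700 nm). The two push-broom cameras see the scene from slightly
different geometry at different spatial resolutions, and each is unreliable
at its spectral extremes. `hsifuse` implements the full chain that turns two
such captures into a single wide-range cube, for researchers evaluating
whether a fused spectrum discriminates classes that neither range resolves
alone (e.g. tissue structures during neurosurgery, or material-and-color
identification of plastics):

1. **Pre-processing** — white/dark reflectance calibration
   `R = (raw − dark)/(white − dark)`, spectral smoothing, band cropping,
   ENVI-style I/O.
2. **Spatial registration** (VNIR fixed, NIR moving) — bilinear upsampling
   of the NIR cube to the VNIR pixel grid, then intensity-based
   (mean-squares, multi-resolution) or feature-based registration: scale
   covariant keypoint detection, ratio-test matching, and MSAC — random
   minimal samples scored with the truncated cost
   `sum(min(r², tol²))` and refit by least squares on the consensus set —
   for translation/similarity/affine/projective models. A coarse-to-fine
   band search (steps of 7 and 3 bands, then 1) finds the band pair that
   registers best by SSIM, and transformation models are compared across a
   dataset by score consistency (lowest IQR among statistically comparable
   candidates).
3. **Spectral fusion** — the operating bandwidth of each camera is derived
   from repeat captures of a flat reference panel via the absolute relative
   difference statistic `RD = 100·|a−b| / ((a+b)/2)`: a band is kept once
   `RD_mean` stays below its band average. The retained NIR segment is
   leveled onto the VNIR segment with a per-pixel reflectance offset, the
   excluded interval between the segments is kept as an explicit gap (no
   interpolation across it), and each pixel's fused spectrum is min-max
   normalized.
4. **Evaluation** — K-means / K-medoids / hierarchical K-means segmentation
   with Jaccard-based cluster-to-class assignment, SVM/RF/KNN pixel
   classification with coarse(-to-fine) hyperparameter search, and paired
   t-tests comparing VNIR-only, NIR-only and fused data.

Because real dual-camera captures are rarely shareable, the package ships a
synthetic scene generator (`make_reference_panel()`,
`make_registration_target()`, `make_plastic_scene()`) with known geometry,
known spectral structure and band-dependent sensor noise, so the whole
pipeline is testable end to end.

## Worked example

```r
library(hsifuse)

# A scene with a known projective misalignment between the cameras
spec  <- scene_spec(vnir_dims = c(128, 128), seed = 3)
scene <- make_registration_target(spec)

fixed  <- gray_from_cube(scene$vnir)
moving <- gray_from_cube(scene$nir)
tm <- register_features(fixed, moving, kind = "projective", seed = 11)

cp <- scene$meta$control_points
sqrt(mean(rowSums((apply_transform(tm, cp$nir) - cp$vnir)^2)))
#> [1] 0.3869352
ssim(fixed, moving)                                  # before
#> [1] 0.09474476
ssim(fixed, warp_image(moving, tm, dim(fixed))$image) # after
#> [1] 0.2397902
```

The estimated transform lands within ~0.4 px of the generator's truth (the
exact value varies by a few tenths of a pixel across scene seeds). SSIM
rises from 0.095 to 0.240 — modest in absolute terms because the two
renderings come from different spectral ranges with different contrast,
but at the ceiling: warping with the generator's *true* transform scores
0.238 on this scene.

Band trimming and fusion on repeat captures of a flat panel:

```r
panel <- make_reference_panel(scene_spec(seed = 5))
nir_up <- upsample_bilinear(panel$nir, dim(panel$vnir$data)[1:2])
cuts_v <- find_cutoffs(relative_difference(panel$vnir, panel$vnir_repeat))
cuts_n <- find_cutoffs(relative_difference(panel$nir, panel$nir_repeat))
fuse(panel$vnir, nir_up, cuts_v, cuts_n)
#> <fused_cube> 96 + 48 bands, gap 939.5-981.4 nm, mean offset 0.0001
```

The noisy 10% of bands at each camera's extremes is cut, the 96 retained
VNIR bands and 48 retained NIR bands are concatenated with their wavelength
gap recorded, and the per-pixel offset (here ~0, the panel is flat) levels
the junction.

## Command line

A thin CLI over the same functions lives at `inst/cli/hsifuse.R`:

```sh
Rscript inst/cli/hsifuse.R simulate --kind plastic --n 2 --seed 1 --dir scenes
Rscript inst/cli/hsifuse.R register --fixed scenes/a/vnir --moving scenes/a/nir --out tm.json
Rscript inst/cli/hsifuse.R run --config pipeline.yml
```

The methods vignette (`vignettes/fusion-methods.Rmd`) documents the model
choices, defaults and limitations.
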