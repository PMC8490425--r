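---
title: "Methods: dual-camera hyperspectral registration and spectral fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-camera hyperspectral registration and spectral fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsifuse)
```

## The problem

A single hyperspectral camera cannot cover 400–1700 nm: silicon sensors
stop near 1000 nm, InGaAs sensors start near 900 nm. A dual-camera rig
therefore produces two cubes of the same scene — VNIR (high spatial
resolution) and NIR (lower resolution) — that differ in geometry, pixel
size, reflectance level and per-band reliability. `hsifuse` builds one
wide-range cube from such a pair and provides the segmentation and
classification harness needed to ask whether the fused spectrum
discriminates better than either range alone. This vignette documents the
models, the defaults, the numerical choices, and what the synthetic
fixtures can and cannot demonstrate.

## Pre-processing

Reflectance calibration is the standard two-point normalization
$R = (\mathrm{raw}-\mathrm{dark})/(\mathrm{white}-\mathrm{dark})$. Where
the denominator is degenerate (dead or saturated elements,
$\mathrm{white}-\mathrm{dark} \le \varepsilon = 10^{-6}$) it is floored
at $\varepsilon$ and the quotient clipped to $[0, 2]$: isolated dead
pixels otherwise dominate intensity-based similarity metrics. A capture
where more than 1% of elements have white $\le$ dark is rejected as a
swapped or broken reference.

Spectral smoothing is a per-pixel moving average along the band axis
(default window 5, configurable): the high-frequency noise being removed
is a property of the sensor readout, not of the spatial scene, so no
spatial filtering is applied. The window shrinks at band edges
(renormalized kernel) rather than padding. No particular filter family is
claimed to be canonical here; the moving average is the simplest
mean-preserving choice and is swappable.

Pseudo-RGB rendering maps the bands nearest 708/539/470 nm to R/G/B for
VNIR cubes; a NIR cube has no visible bands, so a single mid-range band is
replicated (false color). Grayscale conversion uses Rec. 601 luminance
weights. Registration operates on these grayscale renderings, or on a
single min–max-scaled band during the band search.

## Spatial registration

The VNIR image is the fixed frame; the NIR image, first upsampled to the
VNIR pixel size, is the moving one.

**Bilinear upsampling** interpolates each band over the nearest 2×2 source
neighbourhood with corner-aligned coordinates: the corner pixels of the
source map exactly onto the corners of the target, and any bilinear
function of position is reproduced exactly (the basis of the closed-form
tests). Downsampling is out of scope.

**Intensity-based registration** minimizes the mean-squared intensity
difference over the overlap, through a 3-level image pyramid with
Nelder–Mead refinement at each level. Parameters are log-scale/angle for
similarity and matrix perturbations for affine; translations rescale
across pyramid levels. Hypotheses whose overlap falls below 25% of the
frame are rejected with a large penalty, which keeps the optimizer from
"improving" the objective by sliding the images apart.

**Feature-based registration** composes detection → matching → robust
estimation:

* Detectors, behind one interface: `"blob"` (default) is a scale-covariant
  determinant-of-Hessian detector over a σ ladder of 1.2–4.0, with 3×3
  non-max suppression and per-axis quadratic subpixel refinement — the
  same operating principle as the fast-Hessian detectors standard in
  multi-sensor work; `"harris"` for corner-dominated content; `"mser"`
  approximates maximally-stable extremal regions by a threshold sweep
  (step 0.025, both polarities) keeping components whose area is stable
  to the next level (one-sided stability ≤ 0.3) — an approximation of the
  component-tree formulation, adequate as a weaker baseline. Descriptors
  are 8×8 normalized intensity patches sampled at 2× the keypoint scale
  (minimum step 2.5 px), wide enough to span several structure elements
  so that repetitive patterns remain distinguishable; they tolerate the
  small rotations (≤5°) and scale changes (0.9–1.1) of a
  near-perpendicular rig but are not rotation invariant by design.
* Matching: nearest neighbour with Lowe ratio test (default 0.7) and
  mutual-best filtering.
* MSAC: random minimal samples (1, 2, 3, 4 pairs for
  translation/similarity/affine/projective), each hypothesis scored by the
  truncated cost $\sum \min(r^2, \tau^2)$ with $\tau = 1.5$ px, 1000
  trials by default, mandatory seed. The winning hypothesis is refit by
  least squares on its inliers; for the projective model the fit is the
  Hartley-normalized DLT, whose null vector is taken from the
  eigendecomposition of $A^\top A$ so the minimal 4-point system is
  handled uniformly.
* Refinement: two passes of model-guided re-localization — each inlier's
  moving-frame position is re-estimated by normalized cross-correlation
  (13×13 window, ±1 px search at 0.25 px steps, parabolic peak
  interpolation) around the model prediction, then the transform is refit.
  Both images are Gaussian-smoothed (σ = 1) before detection. These two
  steps take median control-point error on the synthetic targets from
  ~0.7 px to ~0.4 px; without them sensor noise dominates keypoint
  localization.

**Band search.** Registration quality depends on which band pair drives
it. The coarse stage scans steps of 7 (VNIR) and 3 (NIR) bands, registering
and scoring each combination; the fine stage repeats at single-band steps
in the winning neighbourhood. SSIM makes the final selection — it responds
to structure, whereas MI and PCC plateau over broad band regions — and
each pair derives its own MSAC seed from the base seed so a pair scores
identically in both stages (hence fine ≥ coarse always). Failed
registrations are recorded as missing and excluded from the argmax; ties
break toward the lowest index pair.

**Model selection across a dataset.** Each candidate transform is applied
to every image pair and scored; candidates significantly below the
highest-mean candidate (paired two-tailed t at 5%) are excluded, and the
lowest interquartile range (type-7, linear-interpolation quartiles) wins
among the rest. The screening step matters: an entirely wrong transform
produces uniformly floor-level scores whose IQR is *small*, so consistency
alone would select it. Consistency is the right criterion only among
models that are statistically comparable in mean quality, which is also
how the accompanying t-test is meant to be read.

## Spectral fusion

**Operating bandwidth.** Push-broom sensors are unreliable at their
spectral extremes. From two captures of the same static scene
(a flat reference panel), the absolute relative difference
$RD = 100\,|a-b| / \tfrac{a+b}{2}$ (symmetric; elements with $a+b=0$
excluded and counted) is averaged over pixels per band (`rd_mean`). A
band is considered reliable once `rd_mean` falls to or below its band
average, and the cutoff rule requires a run of 5 consecutive reliable
bands so that a single quiet band inside a noisy edge is not mistaken for
the operating limit. The rule is scale-free: multiplying the curve by any
positive constant moves the threshold identically. The overlapped
900–1000 nm region is deliberately *not* used for fusion: it lies in the
VNIR sensor's unreliable tail.

**Fusion.** Both cubes are cropped to their cutoffs; each pixel's NIR
segment is shifted by that pixel's reflectance offset — mean of the last
k = 5 retained VNIR bands minus mean of the first k = 5 retained NIR
bands — and the segments are concatenated. The per-pixel (rather than
global) offset keeps the contract local and testable: it exactly levels
the junction for every pixel of a flat target. The excluded interval
between segments is recorded as `gap_nm` and never interpolated across,
preserving the NIR segment's original standard deviation. Finally each
pixel's spectrum is min–max normalized to [0, 1]; constant spectra map to
zero and are counted. The published cutoffs for a real rig of this type
(435/901 nm VNIR, 956/1638 nm NIR, gap 901–956 nm) are available as
`fixed_cutoffs()` defaults in the CLI; `find_cutoffs()` recomputes them
from repeat captures whenever those exist.

## Segmentation and classification

Segmentation runs K-means, K-medoids (PAM, or CLARA above 2500 pixels),
or hierarchical K-means — implemented as bisecting K-means, repeatedly
splitting the largest-inertia cluster until K clusters exist, a standard
reading of the hierarchical variant — on per-pixel-normalized spectra
with Euclidean distance, seeded identically across data types so
comparisons are paired. Clusters map to classes by Jaccard overlap,
greedily in descending score with each cluster used once (the conflict
rule is a design choice; exhaustive assignment agrees on the test toys).
The Jaccard index is intersection-over-union per class over the full
image; accuracy is the fraction of ground-truth-labeled pixels predicted
correctly.

Classification uses SVM (RBF; coarse grid $C,\gamma \in 10^{-3..3}$, then
a 3×3 half-decade refinement), random forest (50–500 trees) and KNN
(odd k ≤ 25), selecting by validation accuracy and touching the test set
once. The benchmark harness (`compare_modalities()`) defaults to KNN with
fixed k = 5: the sweep over 20 scenes × 3 problems × 3 modalities must
stay at desk scale, and the comparison is between data types, not between
classifiers. Fused-vs-best-single differences are tested with a paired
one-tailed t-test at 5%.

## The synthetic scenes

The generators are pure functions of (spec, seed) and emulate three
instrument datasets:

* **Reference panel** — spatially flat 0.95 reflectance, captured twice
  through the noise model; the ground truth for cutoff recovery.
* **Registration target** — a checkerboard with per-cell random albedo
  plus random disks, defined as a continuous function and rendered with
  3×3 supersampling both directly (VNIR) and through the true transform
  (NIR), so stored control points are exact to well below 0.01 px. Random
  truths perturb the identity within rig tolerances: rotation ≤ 5°, scale
  0.9–1.1, shift ≤ 6 px, tilt ≤ 5·10⁻⁴. The per-cell random albedo is
  what makes checkerboard corners distinguishable to a descriptor; a
  binary checkerboard would defeat any local matcher. The NIR target is
  rendered at VNIR size, i.e. in the post-upsampling frame, so control
  point recovery measures registration alone, not interpolation blur.
* **Plastic-like scene** — non-overlapping regions, each assigned a
  (material, color) pair cycling through the full product so collisions
  exist in both directions. Color is a Gaussian reflectance bump
  (centers 70 nm apart, width 45 nm) strictly below 900 nm; material is a
  Gaussian absorption dip strictly above 956 nm; so color is invisible to
  NIR and material invisible to VNIR *by construction*, and the
  material-color problem is unsolvable from either range alone. Pixels
  carry pigment mottling (hue jitter sd 20 nm, concentration jitter 20%,
  dip jitter sd 40 nm), sampled once on the canvas and seen by both
  cameras: without it, classification saturates at 1.0 for several
  modalities and the comparison degenerates to ties, which no real
  instrument produces.

Sensor noise is zero-mean Gaussian, heteroscedastic per band: sd 0.01
(reflectance units) over the interior, 10× over the extreme 10% of bands
at each end, clipped at zero. This reproduces the bathtub shape of the RD
curve without claiming real sensors are Gaussian. Test-scale dimensions
(96×96/48×48 pixels, 120/60 bands; 128×128 for registration targets, 24×24
for panels) keep the full suite under two minutes and the benchmark sweep
under a minute; a `size = "full"` preset (939×743/320×253, 826/172 bands)
matches a real rig.

What passing tests show — and what they do not: the pipeline recovers
known geometry, known bandwidths, and the constructed modality ordering
(VNIR best on color, NIR best on material, fused best on material-color,
mirroring the qualitative finding the harness exists to test). They do not
show performance on real tissue or plastics: the fixtures have no specular
highlights, no spatial illumination structure, no push-broom line timing
artifacts, no inter-band correlated noise, and their class spectra are
idealized Gaussian features.

## Numerical choices and degenerate inputs

* Coordinates are (x = column, y = row) with pixel centers at integers
  starting at 1; transforms act on homogeneous (x, y, 1).
* SSIM: Gaussian 11×11 window (σ 1.5), constants (0.01 L)² and (0.03 L)²,
  averaged over fully supported windows only; dynamic range defaults to
  the joint range of both images. MI bins each image over its own range
  (64 bins) and reports bits; MI(x, x) equals the marginal entropy.
* ENVI dialect: BSQ default, little-endian, float32 (float64 available);
  wavelengths written to 4 decimals; BIL/BIP read and written.
* Largest-rectangle ROI after warping uses the stack-based
  histogram-in-matrix algorithm, O(rows × cols).
* Degenerate cases signal rather than guess: empty cutoff runs,
  overlapping retained ranges (the gap must be non-negative), constant
  images in PCC, too few matches, K exceeding pixels, a class missing
  from a training split.
* Determinism: every stochastic step (captures, MSAC, clustering,
  classifier fits, pixel splits) takes an explicit seed and restores the
  caller's RNG state, so pipeline runs are reproducible from their
  manifest alone.

## Known limitations

Deformable registration is out of scope, as is fusion through the
overlapped 900–1000 nm region and any pan-sharpening beyond bilinear
upsampling. The MSER implementation is a threshold-sweep approximation.
The intensity-based objective is plain mean squares — adequate for
same-modality alignment, weaker across modalities, which is consistent
with feature-based registration being the recommended default. Descriptor
matching assumes the mild geometry of a fixed rig; hand-held capture
would need rotation-invariant descriptors.
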