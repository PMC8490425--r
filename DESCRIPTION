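Package: hsifuse
Title: VNIR-NIR Hyperspectral Image Registration and Spectral Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to combine hyperspectral cubes captured by two push-broom
    cameras covering the visible/near-infrared (VNIR, ~400-1000 nm) and
    near-infrared (NIR, ~900-1700 nm) ranges into a single wide-range cube.
    Provides ENVI-style cube input/output, white/dark reflectance calibration,
    spectral smoothing and band trimming, feature-based and intensity-based
    spatial registration with MSAC robust transform estimation, data-driven
    selection of each sensor's operating bandwidth from repeat captures via
    the absolute relative difference (RD) statistic, reflectance-offset
    spectral fusion with an explicit wavelength gap, and a segmentation and
    pixel-classification harness for comparing VNIR-only, NIR-only and fused
    data. A synthetic dual-sensor scene generator with known geometry, known
    spectral structure and band-dependent sensor noise makes every stage
    testable without access to proprietary captures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    cluster,
    class,
    e1071,
    randomForest,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
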