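Package: ivmotility
Title: Intravital T-Cell Motility, Morphology and Spatial Distribution Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for intravital two-photon time-lapse
    imaging of adoptively transferred T cells in solid tumors. Provides
    synthetic ground-truthed data generation (mixed ballistic, confined
    Brownian, truncated-Levy and stationary-probing motility; rendered
    multi-channel time-lapse stacks with photobleaching, stage drift and
    Poisson-Gaussian noise), image preprocessing (maximum-intensity
    projection, mono-exponential debleaching, phase-correlation rigid
    registration), spot detection and contour segmentation, nearest-neighbour
    track linking with track-length exclusion, per-track motility metrics
    (displacement-based velocity, meandering index), elongation-index
    morphology, four-quadrant behavioural classification, periphery-to-core
    spatial kurtosis heterogeneity, vessel-cell correlation, and cohort-level
    statistics with a normality-gated two-group test and Kruskal-Wallis with
    Dunn's post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
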