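Package: myelometry
Title: Myelin Sheath Morphometry from Cortical Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-mask-driven morphometry of myelinated axons in
    two-dimensional cortical electron-microscopy images: ring-topology
    curation of binary myelin masks, sub-pixel boundary tracing, direct
    least-squares ellipse fitting of the inner (axonal) border, myelin
    thickness sampled at equally spaced ray positions, g-ratio and axon
    diameter estimation with pixel-to-nanometre conversion, cortical layer
    stratification, and per-layer two-group comparisons (Shapiro-Wilk
    screening and unpaired t-tests). Includes a synthetic scene generator
    that renders densely packed elliptical axon cross-sections with exact
    ground truth, so every stage of the pipeline is testable without real
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
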