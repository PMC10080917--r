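Package: aismorph
Title: Axon Initial Segment Morphometry from Fluorescence Line Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies axon initial segment (AIS) geometry from two-channel
    fluorescence microscopy. Extracts arc-length ankyrin-G intensity profiles
    along hand-traced neurites, removes background with a one-dimensional
    rolling-ball (morphological opening) filter, smooths with a first-order
    Savitzky-Golay filter, and locates AIS bounds as the contiguous span
    exceeding half of the baseline-to-maximum dynamic range. Aggregates
    per-neuron measurements into localization proportions and replicate-level
    dimension summaries with explicit exclusion rules, Grubbs outlier
    screening, and chi-square homogeneity tests, and provides masked-image
    intensity metrics (integrated density, Pearson colocalization). Includes
    a synthetic-data generator that renders ground-truth neurons (soma,
    neurite polylines, raised-cosine AIS spans, Poisson-plus-Gaussian noise)
    with a colchicine-like axonopathy mode, so the whole pipeline is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
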