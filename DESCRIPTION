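Package: brainmosaic
Title: Multi-Method Tests for Two-Category Structure in Morphometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether multivariate morphometric or behavioral
    data from two categories (e.g., female and male) form two distinct types
    or a single mosaic population. Implements cross-category k-nearest-
    neighbor anomaly detection with percentile thresholds, unsupervised
    cluster-composition statistics (sex disparity, same-cluster chances,
    disparity-versus-size curves), supervised cross-sample transfer with
    closed-form agreement expectations, allometric power-proportion volume
    correction, diffusion-map and pivoted-QR embeddings, and per-subject
    mosaicism profiling against 33 percent extreme-zone boundaries. A
    synthetic-population generator emulates three contrasting regimes
    (overlapping brain-like data, strongly dimorphic species-like data, and
    large-effect gendered-behavior-like data) plus multi-site variants, so
    the full pipeline is testable without access to neuroimaging datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
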