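Package: attnquality
Title: Assessment of Intrinsic Visual-Attention Qualities from Response Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the systematic assessment of intrinsic visual-attention
    qualities from selective-attention test response sequences (symbolic
    decisions with reaction times). Implements rescaled-range (R/S) analysis
    with least-squares Hurst-exponent estimation (optionally with the
    Anis-Lloyd-Peters finite-sample correction), per-participant feature
    extraction (normalized number of decisions, Hurst exponent, error rate of
    decisions), K-means partitioning with k-means++ seeding and canonical
    cluster ordering, cluster-level second-order statistics (centroids,
    dispersion, covariance, correlation, eigen-features), trace-log-det
    divergence and distance between cluster covariances, an
    information-theoretic metric against the identity covariance, Graham's-scan
    convex hulls, and a four-level quality assignment built from per-factor
    cluster ranks. A deterministic synthetic-cohort generator (exact circulant
    embedding of fractional Gaussian noise) emulates the statistical structure
    of the study data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    readxl,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
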