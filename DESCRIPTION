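Package: feskmeans
Title: Fast, Efficient and Scalable k-Means with k-d Tree Filtering and
    Adaptive Center Updates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Clustering of large geospatial point datasets with the
    FES-k-means algorithm: a hybrid of k-d tree nearest-neighbor filtering
    (midpoint-on-longest-side splits, lossless Kanungo-style candidate
    pruning) and online center updates damped by Mashor's decaying
    adaptation rate.  Includes the classical batch (Lloyd) and online
    (MacQueen) k-means baselines under a shared configuration, cluster
    validity statistics (within-class variance, mean square error in
    decibels, Davies-Bouldin index), per-cluster box-plot outlier
    detection on distances to the assigned center, a subsampling benchmark
    harness, a seeded generator of synthetic Gaussian-blob point data, and
    CSV/JSON/GeoJSON input-output with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
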