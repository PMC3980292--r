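Package: calcistream
Title: Streaming Matrix Factorisation for Real-Time Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A streaming pipeline for functional segmentation of calcium-imaging
    movies. Incoming frames are z-score normalised on the fly, a top-k principal
    subspace is maintained incrementally with candid covariance-free incremental
    PCA (CCIPCA), and extreme "pure-signal" pixel time series are selected with a
    greedy convex-cone algorithm, yielding per-frame low-rank reconstructions and
    an incrementally improving map of neural response units (e.g. antennal-lobe
    glomeruli). Includes an exact offline reference pipeline (batch PCA followed
    by the same convex-cone selection), a synthetic-movie generator with full
    ground truth for validation, real-time display transforms (temporal high-pass,
    incremental min-max colour scaling), and the downstream chemosensing analysis
    (per-stimulus odour feature vectors, Ward clustering, Mantel permutation test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
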