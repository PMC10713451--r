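Package: metacellkit
Title: Metacell Inference by Kernel Archetypal Analysis with a
    Metacell-Level Regulatory Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers metacells from single-cell RNA or ATAC count matrices by
    archetypal analysis of an adaptive-Gaussian-kernel cell-cell affinity
    matrix, optimized by alternating Frank-Wolfe updates with max-min waypoint
    and greedy column-subset initialization. Provides a metacell-level
    regulatory toolkit for scATAC-seq (nucleosome-free fragment filtering,
    Poisson open-peak calling, peak-gene association against GC- and
    accessibility-matched empirical backgrounds, gene scores and gene
    accessibility, transcription-factor activity inference by lasso
    regression), metacell quality metrics (compactness, separation, purity,
    normalized mutual information, density strata, neighborhood mixing
    entropy), cohort-level machinery (cross-sample metacell mapping,
    second-round meta2cells, permutation differential-abundance testing), and
    a synthetic multiome simulator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    RANN,
    irlba,
    RSpectra,
    mgcv,
    glmnet,
    Rcpp,
    IRanges,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
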