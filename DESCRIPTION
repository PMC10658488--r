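Package: vnqi
Title: Vascular Network Quality Index from Binary Vessel Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores engineered microvascular networks by their capacity to
    oxygenate tissue. Binary vessel masks are reduced to six morphological
    metrics (vessel coverage, total vessel length, segment count, branchpoint
    count, mean segment length, mean segment diameter) via skeletonization and
    graph extraction; a steady-state reaction-diffusion oxygen solver provides
    normalized intravascular (OXY_V) and extravascular (OXY_T) oxygen labels;
    and a chained pair of neural networks trained on these labels produces the
    vascular network quality index (VNQI), a single score in [0, 1]. Includes
    a seeded generator of synthetic vasculogenesis-like networks, an
    architecture-comparison harness, correlation ranking, repartitioning
    stability and learning-curve analyses, and a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Matrix,
    methods,
    nnet,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
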