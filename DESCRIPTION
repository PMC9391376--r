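Package: spatialniche
Title: Integrated Spatial and Single-Cell Transcriptomics of the Tumor
    Invasive Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the tumor-stroma invasive niche by combining
    GeoMx digital spatial profiling (DSP) with single-cell RNA-seq, as applied
    to infiltrative basal cell carcinoma. Implements probe-level DSP
    processing (Grubbs outlier QC, geometric-mean probe collapse,
    negative-probe background factors, Q3 normalization) and
    compartment-resolved morphology differential expression; single-cell QC,
    log-normalization, variable-gene selection, SNN graph clustering,
    bin-matched control-gene module scoring and LISI mixing diagnostics;
    inferred copy-number profiles with cross-sample shared-change exclusion;
    cross-contamination filtering of spatial signatures against single-cell
    compartment expression; ranking of tumor subclusters along an
    infiltrative gradient; and a centroid-MST pseudotime with Moran's I
    autocorrelation screening for paracrine driver candidates. A synthetic
    data generator reproduces the statistical structure of both modalities
    with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
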