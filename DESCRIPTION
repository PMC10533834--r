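Package: visdevstats
Title: Genotype-Comparison Statistics for Visual-Brain Cell-Type Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative statistics for asking whether clustered single-cell
    RNA-seq cell types differ between genotypes, built around the design of
    a blind (retinal-ganglion-cell-less) versus wildtype zebrafish study:
    neighborhood genotype-composition permutation z-scores on a kNN graph,
    principal-component alignment with a random-split null, cluster
    transcriptome-alteration and cell-type proportion tests, an in-silico
    cluster-ablation power analysis, and cell-cycle phase scoring with
    zebrafish S/G2M gene sets. Also includes the accompanying HCR-FISH image
    quantification pipeline (per-slice Kapur/Renyi entropy binarization with
    spike-slice fallback and anatomical-mask quantification) and the
    optokinetic-response saccade index, plus synthetic-data generators that
    emulate the study design so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
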