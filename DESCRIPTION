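Package: scdens
Title: Density-Based Clustering and Cell-Cell Crosstalk Analysis for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested implementation of a single-cell RNA-seq workflow
    built around density-based clustering of a tSNE embedding:
    quality-control filters on cells and genes, depth normalization with
    natural-log transformation, per-gene regression of UMI totals, linear
    batch-offset removal, binned-dispersion selection of highly variable
    genes, PCA with a permutation (jackStraw-style) test for significant
    components, two-pass DBSCAN clustering with size-based pruning and a
    removal ledger, two-stage marker-gene calling with a bimodal
    likelihood-ratio test and post-hoc cluster-pair validity checks,
    cluster composition statistics across experimental conditions, and a
    permutation test for ligand-receptor interactions between cell
    populations.  A negative-binomial synthetic-data generator with
    planted populations, marker programs, batch offsets, low-quality
    cells and ligand-receptor programs provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    irlba,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
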