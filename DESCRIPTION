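Package: follimap
Title: Multimodal Intersection Analysis and Ligand-Receptor Scoring for
    Single-Cell and Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control and log-normalization of single-cell and spatial
    UMI count matrices, group-versus-rest marker detection (Wilcoxon rank-sum
    and Welch t tests with Benjamini-Hochberg adjustment), construction of
    thresholded marker gene sets, multimodal intersection analysis (MIA):
    hypergeometric enrichment/depletion maps linking scRNA-seq cell types to
    spatial-transcriptome regions, and ligand-receptor interaction scoring
    between cell types per time point with an empirical permutation null.
    Includes a synthetic count-matrix generator with planted ground truth
    (negative-binomial counts, planted markers, doublets, region programs and
    ligand-receptor channels) so every stage of the pipeline can be exercised
    and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
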