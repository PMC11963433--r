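Package: rejuvenome
Title: Longitudinal Microbiome Rejuvenation Analyses on Synthetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested re-implementation of the computational procedures used in
    life-long fecal microbiota rejuvenation studies in mice: a linear
    mixed-effects interaction screen on microbial metabolic features with
    direction classification and KEGG pathway enrichment, a toy flux balance
    analysis engine with pairwise ecological relationship classification,
    Bray-Curtis community trajectories with rarefaction and principal
    coordinates analysis, single-cell quality control with gene-signature
    module scores and per-cell-type differential expression, and host
    phenotype statistics (trapezoidal AUC, Mann-Whitney, log-rank). Seeded
    synthetic data generators with known ground truth provide every input, so
    the whole pipeline runs end-to-end and its error rates can be measured.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    Matrix,
    survival,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
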