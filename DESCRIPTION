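Package: hapcycle
Title: Cell-Cycle-Resolved Dosage Analysis of Near-Haploid and Diploidized Leukemia Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing near-haploid leukemia cells
    with their diploidized (whole-genome-doubled) counterparts from single-cell
    and bulk expression data. Provides cell-cycle phase assignment from
    metagene signature scores, elliptical cell-cycle pseudo-time with
    rolling-circle trajectory smoothing, graph-diffusion expression imputation,
    ERCC spike-in normalization, stage-specific diploid:haploid dosage-ratio
    and differential-expression analysis against the 2:1 genome-dosage
    expectation, anchor-gene co-expression signatures with hypergeometric
    overlap tests, CRISPR knockout screen depletion calls with ploidy-specific
    intersection logic, DNA-damage focus colocalization statistics, and growth
    kinetics utilities. A synthetic-data module generates all pipeline inputs
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
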