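Package: scase
Title: Allele-Specific Expression States in Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation and classification of allele-specific expression
    (ASE) from single-cell RNA-seq read alignments to a diploid
    transcriptome. Provides read counting by unique reads or by EM
    weighted allocation of multi-mapping reads, a three-state
    beta-binomial mixture model (paternal-monoallelic, bi-allelic,
    maternal-monoallelic) fitted by EM or Gibbs sampling with partial
    pooling of allelic proportions across cells, seven-class ASE pattern
    assignment on the ternary simplex, allelic-bursting independence
    analysis via log-odds ratios with exact tests and FDR control, a
    down-sampling evaluation harness, and a ground-truthed synthetic data
    generator for counts and read-level alignment incidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rsamtools,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
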