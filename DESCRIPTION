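Package: OsmoOmics
Title: Multi-Omics Analysis of Bacterial Hyperosmotic Stress Responses
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis toolkit for bacterial hyperosmotic stress
    studies combining comparative genomics, transcriptomics, proteomics and
    metabolomics. Implements a reciprocal best-hit Smith-Waterman screen for
    osmolyte-related genes across proteomes, a replicate-consistent
    differential expression caller for probe-level two-color microarray
    ratios with positional probe filtering, two-dimensional gel spot
    quantification statistics (total-quantity normalization, low-abundance
    filtering, per-spot one-way ANOVA, fold-change calls, RSD quality
    control and a peptide-mass-fingerprint acceptance rule), GC-MS
    internal-standard relative quantification with per-metabolite t-tests,
    and a genome-ordered hierarchical treemap that overlays transcript and
    protein signals. Synthetic-data generators with planted ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    BiocGenerics,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, Proteomics, Metabolomics, Alignment,
    DifferentialExpression, Visualization
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
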