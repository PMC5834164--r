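Package: refstab
Title: Reference Gene Stability Analysis and Validation for qRT-PCR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selection and validation of qRT-PCR reference (housekeeping)
    genes. Implements RNA-Seq candidate screening by expression stability,
    the four standard Cq-based stability statistics (geNorm M with iterative
    exclusion, NormFinder bias plus variance decomposition, BestKeeper
    descriptive statistics and index correlation, and the comparative
    delta-Ct method), RefFinder-style comprehensive ranking by geometric
    mean of per-method ranks, and multi-reference 2^-ddCt relative
    quantification with Tukey compact-letter significance groups. A
    seeded synthetic-data generator emulating a nematode hatching
    time-course (Cq tables and negative-binomial count matrices with
    planted stable, pulse, drifting and dropout genes) makes every
    pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, Normalization, Transcriptomics
RoxygenNote: 7.3.3
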