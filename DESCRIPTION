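Package: mirproc
Title: Microprocessor Cleavage Fidelity, Small RNA Quantification, and
    Nuclear Condensate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for studies of Microprocessor
    (Drosha/DGCR8) nuclear condensates and miRNA biogenesis in C. elegans.
    Provides a seeded synthetic-data generator (miRNA hairpin references,
    small RNA reads with isomiR end heterogeneity and 3' tailing, FRAP
    time series, hypodermal nucleus images, pri-miRNA feature tables),
    exact-core read alignment with bounded 3' soft-clipping, fractional
    feature counting, piRNA/spike-in size factors and simplified
    differential abundance calling, isomiR-level cleavage-fidelity
    statistics, one-phase-association FRAP fitting (half-time and immobile
    fraction), nuclear focus intensity quantification with session
    normalization, and pri-miRNA feature association tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    minpack.lm,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
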