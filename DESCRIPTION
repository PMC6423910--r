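Package: kitbias
Title: Quantifying DNA Extraction Kit Effects on Abundant and Rare Plankton Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how DNA extraction methods differentially
    affect abundant and rare taxa in replicated amplicon surveys of plankton
    communities. Classifies OTUs into six exclusive abundance categories
    (always abundant through always rare), computes alpha diversity and
    rarefaction curves, four pairwise community dissimilarities (Bray-Curtis,
    Jaccard, unweighted and weighted UniFrac), distance-matrix permutation
    statistics (ANOSIM, one-way PERMANOVA, SIMPER with category roll-ups,
    indicator species analysis), replicate reproducibility per extraction
    method, sequencing-depth sensitivity, Levins niche breadth and occurrence
    overlap, and a low-abundance-filter sensitivity sweep. Includes a
    synthetic community generator that emulates a replicated kit-comparison
    design so the whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
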