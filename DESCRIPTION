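Package: evmir
Title: miRNA qPCR Array Profiling of Cells and Extracellular Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for TaqMan-style low density array (TLDA)
    miRNA quantification-cycle (Cq) data from paired intracellular and
    extracellular-vesicle (EV) samples. Implements detection calling with an
    explicit non-detection sentinel, global-mean normalization on assays
    detected in all samples, empirical-Bayes moderated t differential
    expression with Benjamini-Hochberg adjustment, expressed/non-expressed
    exclusivity calls, EV-enrichment signature classification across cell
    populations, delta-delta-Ct target validation against averaged reference
    genes with Holm-Sidak correction, hypergeometric over-representation
    analysis of predicted miRNA targets, and a synthetic Cq data generator
    with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
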