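Package: heterosisr
Title: Triad Expression Analysis of Biomass Heterosis in Hybrid Crops
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for expression heterosis in a parent/hybrid
    triad (P1, F1, P2). Simulates negative-binomial count triads with planted
    expression patterns, runs a two-group NB Wald test against each parent and
    a mid-parent-value pseudo-sample, classifies features into eight
    P1-hybrid-P2 expression patterns (additive, four expression-level-dominance
    variants, two transgressive, conserved), computes mid-parent and
    better-parent heterosis indices from phenotype tables, scores plant miRNA
    target complementarity, categorizes degradome cleavage sites (categories
    0-4, T-plot tables), and pairs miRNA/target expression for anticorrelation
    analysis, together with the closed-form chlorophyll, 2^-ddCt and cell-size
    assay formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
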