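Package: domnet
Title: Coupled Analysis of Dissolved Organic Matter Composition and
    Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of ultrahigh-resolution mass
    spectrometry profiles of dissolved organic matter (DOM) and 16S
    rRNA-derived bacterial community tables. Implements molecular formula
    assignment for negative-mode FT-ICR-MS peak lists (exact-mass candidate
    enumeration, chemical plausibility filters, heteroatom-combination
    exclusion, cross-sample occurrence filtering, contaminant and isotopolog
    removal, sum normalization), van Krevelen descriptors (double bond
    equivalents, modified aromaticity index, compound-class categorization),
    community table preparation, distance-based multivariate statistics
    (PCoA, ANOSIM-R-maximizing k-R clustering, PERMANOVA, distance-based
    linear models and dbRDA, matrix correlation), LDA effect-size feature
    ranking, and OTU-molecule correlation networks with pivot-table
    summaries and graph export. A synthetic-data generator with known
    ground truth (planted formulas, group structure, collinearity, and
    OTU-molecule correlations) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
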