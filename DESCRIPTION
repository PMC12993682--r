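Package: adassembly
Title: Community Assembly Inference and Succession Statistics for
    Anaerobic Digester Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers the ecological processes behind microbial community
    assembly along successional gradients, with anaerobic digester
    time series as the motivating system.  Implements abundance-weighted
    beta mean nearest taxon distance (betaMNTD), the beta nearest taxon
    index (betaNTI) with tip-shuffle permutation nulls, abundance-based
    Raup-Crick Bray-Curtis (RCbray) partitioning, and the five-way
    classification of sample pairs into variable selection, homogeneous
    selection, dispersal limitation, homogenizing dispersal, or
    undominated assembly.  Also provides the surrounding succession
    statistics (alpha diversity, phase-peak tests with BH-FDR, ANOVA and
    Tukey HSD, PERMANOVA/ANOSIM, PCoA, UPGMA clustering) and a synthetic
    community simulator -- Yule trees, Brownian niche traits, and
    selection/dispersal/drift assembly regimes -- so every inference
    stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
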