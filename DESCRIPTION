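Package: aggprop
Title: Proteome Aggregation Propensity and Chaperonin Dependence from Sequence
Version: 0.1.0
Authors@R: person("Core", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Sequence-only prediction of protein aggregation propensity and
    obligate GroEL (chaperonin) dependence, and a comparative-genomics layer
    relating the predicted proteome fractions (fAg, fC3) to genomic GC content.
    Provides a deterministic protein descriptor engine (composition, gapped
    pair, pseudo amino acid composition, Moreau-Broto/Moran/Geary
    autocorrelation, CTD, quasi-sequence-order, FoldIndex segment statistics),
    training-set curation with greedy identity-based redundancy reduction,
    mRMR feature selection with an RBF-kernel support vector machine trained
    by five-fold cross-validation, proteome scanning, and phylogenetically
    aware statistics (Felsenstein independent contrasts, Kendall correlation,
    Mann-Whitney tests, ANCOVA). Includes seeded synthetic-data generators
    (codon-model proteomes, planted-signal labeled sets, Brownian traits on
    random trees) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
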