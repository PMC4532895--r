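Package: contextpp
Title: Quantitative Modeling of MicroRNA Targeting Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the repression of mRNAs by microRNAs from canonical
    seed-matched sites in 3' UTRs. Implements discovery and classification
    of 8mer, 7mer-m8, 7mer-A1, 6mer and offset-6mer sites; fourteen
    site-level and mRNA-level regression features (target-site abundance,
    seed-pairing stability, local AU content, 3'-supplementary pairing,
    structural accessibility under a local-folding partition function,
    isoform-aware distance and length features, conservation and nucleotide
    identities) with trimmed percentile scaling; per-site-type linear
    scoring with score caps; 3'-UTR tandem-isoform profiles built from
    poly(A)-position (3P-seq) cluster counts, affected-isoform ratios, and
    the cumulative weighted score recursion used to rank predicted targets.
    Also provides the training pipeline: partial-least-squares removal of
    small-RNA-independent structure from fold-change compendia, k-nearest
    neighbor imputation, bootstrap stepwise-AIC feature selection, ordinary
    least-squares model fitting, and evaluation utilities, together with a
    synthetic-data generator that emulates every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
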