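Package: trnarch
Title: Hubs, Colored Motifs and Bow-Tie Architecture of Tissue Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue regulatory networks (TRNs) as expression-induced
    subgraphs of a role-typed reference network over transcription factors,
    microRNAs and non-TF target genes, and analyses their architecture at
    three levels: in-/out-hub identification against Erdos-Renyi random
    ensembles with a tissue-specificity index and degree-redistribution
    sigma_RF curves; colored three-vertex motif detection with
    degree-preserving edge-switch randomization and common versus
    tissue-specific motif classification; and bow-tie decomposition of motif
    instances into input/core/output layers with permutation tests on
    molecular composition and inter-layer average degrees. Includes a seeded
    synthetic-data generator with plantable hubs, motifs and bow-tie layers
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
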