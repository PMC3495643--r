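Package: famaudit
Title: Auditing Family-Level Groupings in Protein Domain Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether family-level groupings inside evolutionary
    superfamilies of protein domains are consistent with phylogenies built
    independently from sequence, structural distance, and functional
    annotation.  Provides neighbour-joining trees with bootstrap consensus
    support, an edge-level agree/disagree/neutral concordance classifier
    against a two-level domain classification, a dustbin-family relaxation,
    ROC-style threshold sweeps, greedy maximum-divergence statistics, and an
    eleven-category placement taxonomy for annotation terms.  Includes a
    synthetic data generator emulating a SCOP-like classification with known
    ground truth, so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
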