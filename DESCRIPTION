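Package: cdtphylo
Title: Phylogenetic Placement of Incomplete Taxa with Concept Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grafts morphologically coded taxa with missing data onto a
    reliable seed phylogeny. Each internal node of the seed tree is turned
    into a decision point carrying multiple concept-sample templates found
    by genetic-algorithm rough-set attribute reduction with an
    entropy-based repair operator; incomplete species are then placed by
    top-down template matching, with species stacking resolved by Wagner
    distances. Includes parsers for NEXUS, TNT and CSV character matrices,
    a discrete-character simulator with known ground truth, path-sequence
    accuracy and parsimony tree-length evaluation, and character
    bootstrapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
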