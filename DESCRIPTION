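Package: netprior
Title: Network-Based Prioritization of Genome-Wide Association Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes genome-wide association study (GWAS) results by
    projecting gene-level association p-values onto protein-protein
    interaction sub-networks. Two-step (radius-2) sub-networks are built
    around every protein in a cleaned interactome, each member gene is
    weighted by a modified PageRank whose damping factor is computed
    dynamically from local connectivity, and weights are combined with
    standardized association z-scores through the Liptak-Stouffer method
    to rank trait-prioritized sub-networks. Includes permutation-based
    null procedures (node-label and GWAS-label permutation), a
    hypergeometric candidate-overlap test, cross-dataset top-network
    comparison, and a synthetic-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
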