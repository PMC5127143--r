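Package: sigmanet
Title: Phylogenetic Classification with Threshold Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one-parameter families of threshold networks from pairwise
    protein similarity matrices, scans the inter-network delta-distance to
    locate critical similarity thresholds, extracts communities as connected
    components, and assembles the corresponding sigma-height dendrogram with
    Newick export. Includes local-alignment-based similarity scoring with an
    E-value validity filter, a recursive sub-community analysis pipeline, and
    synthetic-data generators (planted-block similarity matrices and simulated
    protein families) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
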