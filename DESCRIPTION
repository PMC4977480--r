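Package: sinecr
Title: Signaling Network Inference from Partial RNAi Knockdown Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the topology of a directed signal transduction pathway from
    single-gene-knockdown RNAi outcomes that may be incomplete, guided by a
    reference network from a related organism. Implements a SiNeC-style
    constructor that edits the reference with a small number of edge deletions
    and insertions so that every gene observed to block signal flow (critical
    gene) lies on all receptor-to-reporter paths and no other gene does; two
    critical-gene ranking strategies (classic Sloan profile reduction and
    TopSoG, a topological sort for general graphs built on
    strongly-connected-component condensation and a distance-guided
    depth-first traversal); holistic and prioritized hill-climbing optimizers
    that resolve genes with missing RNAi data, plus an exhaustive baseline; a
    scale-free synthetic benchmark generator with degree-preserving edge
    shuffling; and an evaluation harness reporting edit distance and edge
    F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
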