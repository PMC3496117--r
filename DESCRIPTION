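Package: fimodules
Title: Network Module Discovery for Drug-Resistance Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Turns a list of differentially expressed genes into significant,
    pathway-enriched modules of a functional-interaction (FI) network.
    Implements the full chain used in network analyses of acquired taxane
    resistance: factorial-ANOVA differential-expression selection with
    fold-change and Benjamini-Hochberg FDR filters, mapping onto an FI
    network, shortest-path proximity with a permutation null drawn from the
    largest connected component, average-linkage selection of the
    interconnected core, minimum-spanning-tree inference of linker genes,
    Markov Cluster Algorithm (MCL) partitioning with size filters, and
    binomial pathway enrichment with a permutation false discovery rate.
    A synthetic-data module generates scale-free interactomes with planted
    dense modules and matched two-color expression data with known ground
    truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
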