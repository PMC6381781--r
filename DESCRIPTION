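Package: baitnet
Title: Bait-Seeded Qualitative Co-Expression Network Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Screens expression compendia for genes co-expressed with
    user-chosen bait genes using a qualitative, biclustering-style matching
    score (the BF value) that detects correlation confined to condition
    subsets as well as global correlation. Provides rank-quantile
    discretization of normalized expression matrices, an exact and a
    permutation null for the pair score, bait-anchored network construction,
    extension with transcription-factor baits, cross-species homolog overlay
    from BLAST tabular hits, functional-bin enrichment by Fisher's exact test
    with Benjamini-Hochberg control, intersection with differential-expression
    lists, a Pearson-correlation comparator, and a planted-module synthetic
    expression generator for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
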