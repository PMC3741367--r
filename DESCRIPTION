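Package: linctools
Title: Discovery and Characterization of Large Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for cataloguing large intergenic noncoding
    RNAs (lincRNAs) from assembled transcript models and per-tissue
    expression. Implements a five-step filter cascade (expression support,
    annotation-overlap exclusion, alignment-free coding-potential
    classification by adjoining-triplet log-odds, structural thresholds,
    intergenic distance), Jensen-Shannon tissue-specificity scoring,
    replicate-recurrence statistics, TSS-centered histone metagene profiles,
    Markov clustering of two-color co-expression networks with
    hypergeometric GO enrichment, and nearest-coding-neighbor correlation
    analysis with a randomized GO-sharing null. A seeded synthetic-data
    generator emulates every input with planted ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
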