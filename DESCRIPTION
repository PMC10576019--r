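Package: dbgsplice
Title: Reference-Free Alternative Splicing Detection from Transcript Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and types the seven canonical alternative splicing event
    classes (exon skipping, alternative acceptor, alternative donor, intron
    retention, alternative first/last exon, mutually exclusive exons) directly
    from full-length transcript sequences, without a reference genome. Each
    candidate transcript pair is compared in a colored de Bruijn graph built at
    a dynamically selected k; bubble topology separates single-nucleotide
    variants from splicing, unresolved bubbles are refined with smaller k-mers
    in a mixed-k graph, and AF/AL/MX events are called by graph position. The
    remaining four classes are typed by a gradient-boosted tree classifier on
    splice-site sequence and motif features. A percent-spliced-in module tests
    differential splicing across conditions with permutation tests, and a
    seeded simulator generates ground-truthed fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
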