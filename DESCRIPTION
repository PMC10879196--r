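Package: mgeflow
Title: Gene Flow Between Phages, Plasmids and Phage-Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies recent gene exchanges between mobile
    genetic elements (phages, plasmids and phage-plasmids) from all-vs-all
    protein alignment tables. Implements bidirectional best-hit extraction,
    weighted gene repertoire relatedness (wGRR), recombining-gene detection
    via high-identity homologs between otherwise dissimilar elements,
    single-linkage clustering of recombining genes into families,
    exchange-type counting against a label-permutation null, functional
    enrichment with Fisher exact tests, Benjamini-Hochberg correction and
    difference-sum ratios, a relatedness screen against a reference
    phage-plasmid group with persistent-genome extraction, and a seedable
    synthetic-collection generator with planted transfers for validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
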