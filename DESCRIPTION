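Package: promloop
Title: Downstream Analysis of Promoter Capture Hi-C Interaction Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and integrative analysis of promoter capture
    Hi-C (PCHi-C) significant-interaction calls. Implements replicate
    consensus filtering with 1 kb-extension matching, cell-type specificity,
    interaction categorisation and distance summaries; TAD and A/B
    compartment integration; randomized restriction-fragment background
    enrichment for chromatin features, expression-binned enrichment and the
    peak-density/expression correlation; LD expansion of GWAS tag SNPs and
    SNP-to-target-gene linking through chromatin loops; a promoter-remapping
    permutation test for eQTL-loop enrichment; gene-set resampling and
    hypergeometric GO enrichment with ontology parent propagation. A
    synthetic-data generator with planted parameters makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
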