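Package: serumchallenge
Title: Comparative Serum-Challenge Genomics for Human and Chimpanzee Fibroblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for two-species fibroblast serum-challenge
    experiments combining RNA-seq and DNase-seq. Implements trimmed-mean
    (TMM) normalization and negative binomial GLM likelihood-ratio
    differential testing of ortholog count matrices, running-sum gene set
    enrichment with permutation significance, hypergeometric category
    enrichment against a user-defined background, harmonization of
    per-sample DNase-hypersensitive-site peak calls into comparable
    cross-species windows with sharing classification, fuzzy c-means
    clustering of chromatin-accessibility trajectories, nearest-TSS
    peak-to-gene linking with accessibility/expression correlation,
    dN/dS gene-set tests and a promoter-versus-intron human-branch
    substitution-rate likelihood-ratio test, and a synthetic-data
    generator that plants known effects so the whole pipeline can be
    validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fgsea,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    e1071,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
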