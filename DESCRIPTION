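Package: polyexpress
Title: Homoeolog Expression Bias, Temporal Expression Shifts and
    Co-Expression Asymmetry in Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gene-level RNA-seq count data from
    allopolyploid species with paired homoeologs on two subgenomes, built
    around cotton (Gossypium) fiber development time courses.  Calls
    per-pair subgenome expression bias with Fisher's exact test on pooled
    read counts, a two-fold FPKM change rule and Benjamini-Hochberg FDR
    control; summarises bias per cultivar and stage, forms strict
    cross-cultivar consensus patterns and classifies interspecific bias
    categories.  Soft-clusters developmental expression profiles with
    fuzzy c-means, assigns per-gene peak stages and detects temporally
    postponed expression between species.  Builds weighted co-expression
    networks (soft-thresholded adjacency, topological overlap, module
    eigengenes, kME module membership, hub genes, top-weight edge lists).
    Includes a negative-binomial simulator that plants known bias,
    peak-stage shifts and co-expression modules, plus recovery metrics
    for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    withr,
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
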