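Package: selnet
Title: Coexpression and Cosplicing Network Analysis for Selectively Bred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-centric analysis of bulk RNA-Seq from bidirectionally
    selected lines (for example high versus low voluntary drug intake).
    Implements upper-quartile CPM normalization and expression filtering,
    per-line Pearson coexpression and Mantel-correlation cosplicing networks
    with consensus module detection on topological overlap, scale-free
    topology checks, connectivity culling and hub identification,
    differential expression, differential wiring and exon-equal differential
    splicing with shared-schedule permutation nulls, Fisher's-exact module
    enrichment and protection tests, selection-phenotype statistics
    (realized heritability, intake and preference arithmetic, delta-delta-Ct),
    and a seeded synthetic-data generator with planted modules, expression,
    wiring and splicing effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
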