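Package: polynet
Title: Duplicated Coexpression Network Analysis for Allopolyploid Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing weighted gene coexpression networks built from
    homoeolog-resolved RNA-seq count data in allopolyploids. Provides a
    negative-binomial differential-expression layer (likelihood-ratio and Wald
    tests, homoeolog-bias contrasts), WGCNA-style network construction
    (soft-thresholded adjacency, topological overlap, average-linkage module
    detection, module eigengenes and kME), permutation-based module preservation
    (Zsummary and medianRank), per-module homoeolog expression-bias chi-square
    tables, differential correlation between condition groups (Fisher z, local
    FDR, binomial DC-gene model), kME-ranked gene-set enrichment, and a
    negative-binomial simulator of homoeolog-pair counts with planted modules,
    expression bias, co-module divergence and network rewiring for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
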