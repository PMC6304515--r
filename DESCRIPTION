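Package: mirrewire
Title: Correlation Rewiring of Validated miRNA-Target Pairs Between Tumor
    and Normal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated miRNA-mRNA coexpression pipeline for bulk RNA-seq
    read counts. Screens differentially expressed miRNAs and genes between
    healthy controls and early/advanced stage tumors, intersects them with
    experimentally validated miRNA-target interactions, identifies critical
    pairs by significant negative Pearson correlation in normal tissue,
    quantifies the loss of that anticorrelation in tumors (including a
    paired tumor/normal design and a delta-r statistic), aggregates results
    across cancer types into frequency tables and a pan-cancer bipartite
    regulatory network, and runs hypergeometric gene-set enrichment of the
    target genes. Ships a seeded Gaussian-copula negative-binomial cohort
    simulator with planted fold changes and planted pair coupling for
    ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
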