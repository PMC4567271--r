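Package: mirpairs
Title: Integration of miRNA Direction Tables and Multi-Cohort Expression
    Data to Call Anticorrelated miRNA/mRNA Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate miRNA-regulated genes in rheumatoid
    arthritis (RA) by integrating a literature-curated table of
    dysregulated miRNAs with multi-cohort gene expression data. Consensus
    target sets are built by intersecting two prediction sources (with a
    single-source fallback), two-group differential expression is computed
    on microarray (log2 intensity) and RNA-seq (FPKM) series, genes that
    are also differentially expressed between the osteoarthritis and
    healthy control groups are removed as disease-nonspecific false
    positives, multi-series sign-consistency filters select strict- and
    relaxed-tier candidates, and (miRNA, gene) pairs whose expression
    directions oppose each other are called and exported as a bipartite
    regulatory network (SIF/GraphML). Includes hypergeometric gene-set
    enrichment over user-supplied GMT collections and a synthetic
    multi-cohort data generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    xml2
Config/testthat/edition: 3
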