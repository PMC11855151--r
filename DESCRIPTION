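Package: lncnet
Title: lncRNA-mRNA Regulatory Network Analysis for Differential-Expression
    Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for systems-level analysis of long
    non-coding RNA (lncRNA) regulation from differential-expression
    results. Filters DESeq2-style result tables at configurable
    significance thresholds, classifies transcripts by ENSEMBL biotype,
    intersects significant transcripts with lncRNA-mRNA interaction
    predictions to build a bipartite regulatory network, ranks lncRNAs by
    degree centrality, clusters them by structural equivalence (shared
    mRNA targets), performs hypergeometric over-representation analysis
    of target genes against GMT gene-set collections with
    Benjamini-Hochberg correction, and computes pairwise alteration
    co-occurrence / mutual-exclusivity statistics (odds ratios and Fisher
    exact tests) from binary sample-by-gene alteration matrices. A
    synthetic-data generator with planted hubs, equivalence blocks,
    enriched sets and co-altered pairs makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    ape,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
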