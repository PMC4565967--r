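Package: lncoex
Title: Co-Expression-Based Functional Annotation of Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-coding genes co-expressed with long non-coding
    RNAs (lncRNAs) in matched RNA-Seq expression matrices, using simple linear
    regression or Spearman rank correlation with significance testing of the
    coefficient. Co-expressed gene (CEG) sets are merged across lncRNAs and
    across datasets by union or intersection, tested for GO and KEGG gene-set
    enrichment with the hypergeometric distribution under Bonferroni or
    Benjamini-Hochberg correction, and exported as bipartite lncRNA-gene
    co-expression networks for Cytoscape. Includes a synthetic-data generator
    with planted co-expression structure and planted enriched terms, and a
    command-line interface mirroring the analysis modules.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
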