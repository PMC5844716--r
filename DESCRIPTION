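Package: hubgene
Title: Hub-Gene Discovery from Two-Group Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate hub genes from small-replicate two-group
    expression experiments. Screens differential genes with a random-variance-
    model (RVM) moderated t-test and Benjamini-Hochberg FDR, scores gene-set
    over-representation with Fisher's exact and chi-square tests and the
    enrichment ratio Re = (nf/n)/(Nf/N), builds directed GO-term maps,
    significant-pathway interaction networks, curated-interaction signal
    networks ranked by betweenness centrality, and per-group Pearson
    co-expression networks with k-core decomposition, then intersects the
    evidence streams to nominate hub genes. Includes a fully seeded synthetic
    data generator with planted differential genes, enriched terms and network
    hubs, and 2^-ddCt relative quantification for qPCR validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
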