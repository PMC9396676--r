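Package: oranet
Title: Over-Representation Analysis of Chemical-Gene Associations and
    Drug-Gene Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico drug repurposing from curated disease gene
    sets. Loads chemical-gene association tables in the style of CTD and
    STITCH exports, scores each compound by the hypergeometric upper-tail
    over-representation statistic with Benjamini-Hochberg false discovery
    rate control, applies blocklist filtering and cross-source
    consolidation, and reconstructs bipartite drug-gene (and gene-pathway)
    networks with density, degree, closeness and edge-betweenness metrics.
    Ships a synthetic association-database generator with planted enriched
    compounds so the full pipeline, including its type-I-error calibration
    and power, is testable without external downloads.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
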