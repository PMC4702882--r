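Package: ognest
Title: Hierarchically Consistent Orthologous Groups from Protein Similarity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds orthologous groups (OGs) of proteins from an all-vs-all
    sequence similarity matrix, independently at nested taxonomic levels, and
    enforces hierarchical consistency between levels by splitting and merging
    groups guided by species overlap. Derives fine-grained pairwise orthology
    (one-to-one, one-to-many, many-to-many) from rooted gene trees using
    species-overlap duplication inference, and summarizes and propagates
    functional annotations (free-text descriptions, COG categories, GO/KEGG/
    SMART/Pfam term frequencies) across the OG hierarchy, including merging of
    groups by shared Pfam clan-level domain architecture and in-silico
    polyprotein cleavage. A gene family birth-death simulator generates
    species trees, gene trees with known duplication and loss history, noisy
    bit-scores and ground-truth OG partitions per level, so every component is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
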