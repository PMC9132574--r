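Package: gcdark
Title: Validation, Classification and Ecology of Gene Clusters from the
    Unknown Sequence Space
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to validate metagenomic and genomic gene clusters,
    partition them into Known, Known-without-Pfam, Genomic-Unknown and
    Environmental-Unknown categories, aggregate them into gene-cluster
    communities by Markov clustering of a profile-homology graph, and
    characterize their environmental distribution (Levins niche breadth
    with count-preserving null models) and phylogenomic signal
    (lineage-specificity F1 score, consenTRAIT phylogenetic conservation).
    Includes a seeded synthetic-data generator that emulates every input
    the pipeline consumes, with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    vegan,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
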