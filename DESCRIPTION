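Package: famcontent
Title: Protein-Family Content Analysis of Prokaryotic Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares prokaryotic genomes by their protein-family content.
    Implements two-step homology clustering (greedy set cover of a filtered
    sequence-similarity network followed by Markov clustering of a
    profile-profile match network), genome quality control from single-copy
    gene inventories with de-replication, presence/absence matrix
    construction and prevalence filtering, detection of co-occurring family
    modules on a Jaccard co-occurrence network with Louvain community
    detection and median-m taxonomic assignment, content-based dendrograms
    with cophenetic comparison to phylogenies, branch collapsing with
    per-group wedge counts, and Fisher-exact enrichment categorization of
    families between two genome collections with Benjamini-Hochberg
    correction.  A synthetic pangenome generator with planted module and
    enrichment structure makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    ape,
    Biostrings,
    jsonlite,
    mclust,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
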