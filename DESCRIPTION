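Package: ancgene
Title: Ancestral Gene-Content Reconstruction for Reduced Symbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for studying genome reduction in
    bacterial endosymbionts. Clusters proteins into ortholog families by
    best-hit transitive closure over all-vs-all cross-genome local
    alignments, applies length- and domain-based pseudogene and artifact
    annotation rules, reconstructs the ancestral gene content of an ingroup
    genus from ingroup and outgroup genomes, assigns lineage-specific
    losses, inactivations and acquisitions with a Pearson chi-square
    loss-count comparison, and tests purifying selection on shared
    pseudogenes with Nei-Gojobori Ka/Ks. A built-in gene-content evolution
    simulator with a full event ledger makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
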