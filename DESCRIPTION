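Package: mrptree
Title: Matrix Representation with Parsimony Supertree Construction and Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building supertrees from collections of
    overlapping source phylogenies under a strict curation protocol. Provides
    rooted-tree input/output (Newick and NEXUS), nomenclature standardisation
    with user-defined substitution rules (synonyms, higher-taxon and genus
    expansion, paraphyletic-taxon permutation with mini-supertrees),
    non-independence and taxonomic-overlap checks, Baum-Ragan matrix
    representation with parsimony (MRP) coding with an all-zero hypothetical
    outgroup, TNT and NEXUS matrix input/output, parsimony tree search
    (stepwise addition with NNI/SPR hill climbing, plus an exhaustive oracle
    at small sizes), strict consensus and agreement-subtree summarisation,
    post-hoc diagnostics (resolution, novel clades, rogue taxa, data
    availability), and a synthetic source-tree generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
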