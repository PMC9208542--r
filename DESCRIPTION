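Package: dnaserep
Title: Classification and Evolutionary Dating of the Vertebrate DNase Repertoire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to define and date the vertebrate repertoire of DNase1- and
    DNase2-family endonucleases. Builds one profile hidden Markov model per
    orthogroup from a curated alignment, scores proteins with forward and
    Viterbi algorithms, calibrates E-values against a Gumbel null, and assigns
    proteins to orthogroups by best match. Diagnostic sequence features
    (disulfide-forming cysteine pairs, GPI-anchor omega sites, C-terminal basic
    peptides, somatomedin-B cysteine stretches, signal peptides, and
    phospholipase-D HxK motifs) verify the assignments. Presence/absence
    matrices across taxa are reconciled with a dated species tree by Dollo
    parsimony to place gene gains and losses in time, tandem duplications are
    dated from gain-branch intervals, and local gene arrangements (tandem,
    head-to-head, tail-to-tail) are detected from coordinate tables. A seeded
    synthetic-data generator produces ground-truthed proteomes, histories, and
    gene tables so the whole chain can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
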