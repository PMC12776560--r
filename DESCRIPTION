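Package: rnascore
Title: Scoring and Model Selection for Coarse-Grained RNA 3D Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for RNA 3D structure predictions represented by
    one C1' atom per nucleotide. Implements the length-normalized TM-score with
    its RNA-specific d0 scaling, sequence-dependent TM-score and
    sequence-independent TM-align (dynamic-programming alignment with iterative
    superposition refinement), SVD-based Kabsch superposition and C1' RMSD,
    competition-style leaderboard aggregation (best-of-five over alternative
    ground-truth conformations, mean over targets, two-pass outlier-trimmed
    Z-score ranking, paired group comparisons), a weighted greedy selector that
    assembles a diverse five-conformation ensemble from multi-model candidate
    pools, and a synthetic C1' chain generator (ideal helices, self-avoiding
    coils, bent two-helix chains) so the whole pipeline can be exercised
    without external structure downloads. Includes PDB and CSV readers/writers
    for the formats involved and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
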