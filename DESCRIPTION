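Package: repdrift
Title: Longitudinal Analysis of Antibody Repertoire Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying drift and persistence in adaptive immune
    receptor repertoires (AIRR-seq) sampled from the same subjects at multiple
    timepoints. Collapses annotated heavy-chain rearrangements into clonotypes
    (V gene, J gene, CDRH3 amino-acid sequence), computes Morisita-Horn
    similarity over (V gene, J gene, CDRH3 length) species with bootstrap
    rarefaction, estimates sequence- and clonotype-level turnover and
    persistence between timepoints, characterizes persistent and public
    clonotypes (isotype, somatic hypermutation, clonal expansion, CDRH3
    sequence logos), and classifies replicate repertoires by subject and
    timepoint from gene-usage features with leave-one-replicate-out
    evaluation. A configurable synthetic V(D)J repertoire simulator with a
    ground-truth lineage registry makes every analysis stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    jsonlite,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
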