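Package: ontorep
Title: Annotation and Longitudinal Lineage Analysis of B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating bulk B-cell receptor (BCR) sequencing reads
    against a germline gene library, extracting CDR3 junctions, identifying
    transcripts that belong to the clonal lineage of known "seed" antibodies
    (identity-divergence islands, iterative intradonor phylogenetic analysis,
    CDR3 clustering), and reconstructing the development of a lineage across
    longitudinal time points with birthday-labelled maximum-likelihood trees
    and inferred ancestral intermediates. Includes a synthetic-repertoire
    simulator with recorded ground truth so the whole pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    grDevices,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
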