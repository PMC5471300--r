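Package: coevomap
Title: Direct Coupling Analysis, Structural Contact Validation and
    Iterative Paralog Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Co-evolutionary analysis of protein families. Infers Potts
    models from multiple sequence alignments by asymmetric
    pseudo-likelihood maximization (plmDCA) or mean-field inversion,
    scores residue pairs with gap-excluded Frobenius norms and the
    average product correction, validates predicted contacts against
    heavy-atom structural contact maps including a shortest-path
    mediation analysis, and pairs interacting paralogs across organisms
    with the Iterative Paralog Matching procedure to predict
    inter-protein contacts. Ships a synthetic-data generator (planted
    contact topologies, Gibbs-sampled alignments, toy structures,
    paired paralog families) with known ground truth for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
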