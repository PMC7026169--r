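Package: edura
Title: Axis-Systematic Analysis of Chromosomally Embedded Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint structural and functional analysis of bacterial gene
    regulation on a circular chromosome. Implements the EDURA statistic
    (edge distribution under rotation of an axis) for detecting a
    systematic Ori-Ter axis in a chromosomally embedded transcriptional
    regulatory network, degree-preserving switch randomization and
    planted-axis random-network generators for calibration, digital and
    analog control-strength z-scores (CTC) for differential-expression
    contrasts against gene and proximity network null models, and
    shuffle-corrected decision-tree feature importances relating
    chromosomal and network features to expression changes. Includes a
    synthetic-data module generating genomes, hub-dominated networks,
    binding sites and contrast matrices with a controllable mixture of
    network-spreading and chromosomal-neighborhood mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
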