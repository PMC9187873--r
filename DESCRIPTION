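Package: subpopscreen
Title: Subpopulation-Aware Digital Cytometry for Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns undetermined cell subpopulations from single-cell RNA-seq
    by multi-level archetypal analysis, builds a subpopulation signature
    matrix, estimates subpopulation fractions in bulk expression profiles by
    batch-adjusted support-vector regression, quantifies per-subpopulation
    drug susceptibility and treatment consistency from perturbation screens,
    and searches greedily for a minimal drug cocktail that kills every
    killable subpopulation.  Includes a synthetic-data generator emulating
    subpopulation-structured cells with batch and cell-cycle nuisance signal,
    platform-shifted bulk mixtures of known composition, and dose-laddered
    perturbation screens with known per-subpopulation kill rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    e1071,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
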