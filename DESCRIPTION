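Package: epipotts
Title: Cellular Potts Simulation of Epithelial Layer Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-dimensional Cellular Potts Model of epithelial cells
    proliferating on a substrate. Implements the Potts energy functional
    (area compressibility, cortical contractility, differential adhesion),
    Metropolis Monte Carlo dynamics with an exact incremental energy change,
    adhesion-dependent cell division via a Hill function of the number of
    cell-substrate adhesion sites, oriented mitosis (vertical, horizontal,
    random, and major-axis division planes), a closed-form rectangular-cell
    equilibrium for single-cell morphology, snapshot morphometrics with
    monolayer/multilayer classification, and reproducible parameter sweeps
    for regenerating single-cell and collective morphology phase diagrams.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
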