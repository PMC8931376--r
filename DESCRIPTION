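Package: cbclabel
Title: Labeling Kinetics and Isotopically Nonstationary Flux Analysis of the
    Calvin-Benson Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 13CO2 labeling time courses of photosynthetic
    metabolism. Parses compartmentalized atom-mapped reaction networks of the
    Calvin-Benson cycle, the photorespiratory pathway and the cytosolic
    glucose-6-phosphate shunt; simulates transient mass isotopologue
    distributions by elementary metabolite unit (EMU) decomposition; fits
    nested polyexponential decay models to percent-12C time courses with
    extra-sum-of-squares, cross-validation, AIC and BIC model selection;
    fits fluxes and pool sizes to isotopologue measurements by weighted
    nonlinear least squares and compares unlabeled-carbon-entry model
    variants; and provides isotopologue diagnostics for the overabundance
    of fully unlabeled molecules. Includes a synthetic-data generator with
    known ground truth emulating leaf labeling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
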