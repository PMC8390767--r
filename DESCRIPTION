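Package: mpbnssfp
Title: Transient-State Multiparametric MRI Mapping with Composite Balanced
    Propagators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete affine-propagator description of the magnetization
    evolution in repeated-block balanced MRI sequences, with exact
    closed-form matrix powers (real-valued Putzer form), eigenvalue-space
    sequence design diagnostics, Cramer-Rao lower-bound optimization of
    multi-phase excitation schemes, synthetic vial-phantom simulation, and
    simultaneous voxelwise estimation of T1, T2, proton density, B0, B1 and
    the per-block dissipation (HO) map from a single transient echo train,
    plus synthesis of weighted contrasts from the fitted maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
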