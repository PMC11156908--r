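Package: picoflux
Title: Isotopically Nonstationary 13C Metabolic Flux Analysis for
    Compartmentalized Photoautotroph Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits transient 13C-bicarbonate labeling
    experiments in compartmentalized photoautotroph metabolic networks.
    Provides an atom-transition network parser, elementary metabolite unit
    (EMU) decomposition, stiff-capable integration of transient EMU
    balances with a brute-force isotopomer oracle, multi-start nonlinear
    least-squares flux estimation with chi-square goodness of fit and
    profile-likelihood (parameter continuation) confidence intervals,
    CO2-normalized flux maps, mass-balanced biomass composition handling,
    ATP/NADPH energetics ledgers, and a synthetic-experiment generator
    with carbohydrate-rich and protein-rich carbon-partitioning scenarios.
    Includes small chlorophyll-fluorescence utilities (NPQ, single-turnover
    flash schedules, inhibitor effect tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
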