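Package: kcsafilter
Title: Reduced Molecular Dynamics of the KcsA Selectivity Filter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A femtosecond-resolution, reduced molecular-dynamics model of the
    KcsA potassium-channel selectivity filter: four strands of carbonyl groups
    with fixed carbons, harmonically vibrating oxygens carrying split
    oxygen/lone-pair point charges, and single-file axial transport of K+ ions
    and rigid water molecules.  Velocity-Verlet integration with an
    Andersen-style 310 K bath on the carbonyl rotors, stochastic injection at
    the cavity site and emission detection at the extracellular exit drive
    conduction statistics.  Experiments cover the conduction-rate versus
    filter-length scan with Gaussian curve fitting, carbonyl-oxygen
    fluctuation statistics, occupancy-pattern coding, event/residence
    statistics, and test-charge potential profiles with S1-S0 barrier
    extraction.  Analysis results are returned as tibbles with ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
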