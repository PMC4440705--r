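Package: mitoqc
Title: Stochastic Simulation of Mitochondrial Quality Control and mtDNA
    Heteroplasmy Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An exact stochastic simulator (Gillespie direct method) of
    mitochondrial quality control in a spatially compartmentalized cell.
    The model tracks wild-type and mutant mtDNA nucleoids inside
    individual mitochondria and simulates four reaction classes:
    retrograde-regulated nucleoid replication, selective mitophagy,
    selective pairwise fusion between mitochondria in the same or
    adjacent cell compartments, and fission with random nucleoid
    segregation.  The package ships the premixing and mixing-time
    calibration protocol, scenario presets for clonal-expansion
    experiments, statistics of transient mutant-rich mitochondria, and a
    variance-based (RS-HDMR) global sensitivity analysis over a Latin
    hypercube design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
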