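Package: fentonsim
Title: Generalizable Kinetic Modeling of Fenton and Photo-Fenton Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates Fenton and photo-Fenton degradation of organic
    contaminants in a recirculating pilot plant. The degradation mechanism of
    a target compound is generated algorithmically from its carbon number as a
    cascade of halving breakage steps with fictitious lumped fragments, and is
    coupled to a simplified radical core (Fe2+/Fe3+ cycling, photo-reduction,
    first-order hydroxyl-radical elimination) with a competitive-rate
    normalization of the reactions that consume HO*. Includes total organic
    carbon bookkeeping, mineralization stoichiometry, a four-compartment
    reactor model with finite-time oxidant feed, staged parameter estimation
    (core constants from blank assays, then two target-specific constants per
    compound) and a synthetic-data generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
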