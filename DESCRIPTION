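Package: actipoly
Title: Brownian Dynamics and Rheology of Tangentially Driven Entangled Polymer Melts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics for melts of tangentially
    self-propelled bead-spring (Kremer-Grest) polymers, together with the
    analyses needed to characterise their viscoelasticity and topology:
    virial stress sampling, multiple-tau stress autocorrelation, plateau
    modulus and disengagement-time extraction, Green-Kubo time-dependent
    viscosity, storage and loss moduli, scaling collapses, and a geometric
    primitive-path contraction yielding entanglement lengths and kink
    counts. Includes melt construction, soft push-off and bond-swap
    Monte Carlo equilibration, extended-XYZ and LAMMPS-dump trajectory
    input/output, and an end-to-end pipeline driver.
License: MIT + file LICENSE
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
    jsonlite,
    yaml,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
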