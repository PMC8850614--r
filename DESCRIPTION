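Package: swarmsir
Title: SIR Contagion on Self-Organized Swarms of Self-Propelled Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of susceptible-infectious-recovered (SIR)
    contagion coupled to the collective motion of self-propelled particles with
    polar alignment, soft-core repulsion and angular noise in a periodic
    two-dimensional arena. Provides the spatial integrator, synchronous SIR
    dynamics on the evolving proximity graph, order parameters (polarization
    and largest-cluster fraction), collective-state classification, density
    rendering, contact statistics, a homogeneous-mixing final-size baseline,
    and replicate-ensemble sweep protocols over the Peclet number, alignment
    strength, infection-lifetime transmissibility and infectious duration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
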