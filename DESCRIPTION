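Package: agesim
Title: Agent-Based Energy-Allocation Simulation of the Evolution of Aging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, agent-based model of an evolving population in which
    heritable maturation ages and intrinsic death times compete for a shared,
    saturating energy pool under starvation, density-dependent predation and
    energetically costly mating. Individuals allocate foraged energy to growth,
    somatic repair and metabolism; maturation and longevity are inherited
    biparentally with multiplicative mutation, so life-history schedules evolve
    over hundreds of generations. The package provides the per-iteration engine
    (compiled, with an exact pure-R reference stepper), replicate runners with
    survival and energy-allocation statistics, and a simulated-annealing search
    with monotonic-trend scoring that identifies parameter regimes in which
    increased predation selects for shorter (classical) or longer (non-classical)
    evolved lifespans, together with presets for both regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
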