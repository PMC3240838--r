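Package: turntaking
Title: Evolutionary Agent-Based Simulation of Turn-Taking and Contest
    Strategies in Animal Conflict
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of conflict strategies in group-living
    animals. Individuals repeatedly enter dyadic conflicts over a resource;
    whether a conflict escalates into a costly fight is governed by
    dyad-specific willingness-to-escalate values that are updated after each
    decided conflict through a heritable update factor. Escalated fights are
    resolved by a sequential-assessment process in which each fighter
    accumulates noisy evidence of being the weaker opponent and concedes when
    the evidence crosses a heritable giving-up threshold. Generations consist
    of a conflict phase, fitness-proportional reproduction with mutation, and
    migration of offspring between groups. The package provides the full
    generational simulator (with a compiled core for sweep-scale runs),
    dominance-structure metrics (directional consistency index, Landau
    linearity with randomization over undecided dyads), strategy
    classification, and experiment drivers for benefit sweeps, two-strategy
    competition experiments and sensitivity analyses, plus a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
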