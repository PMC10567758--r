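Package: virofate
Title: Stochastic Within-Host Virus Infection Dynamics with Post-Entry
    Infection Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the fate (extinction versus establishment) of
    within-host virus infections seeded by a small number of infectious
    virions or cells. Implements a discrete, integer-valued stochastic model
    of target-cell-limited infection kinetics with Erlang-staged eclipse and
    infectious phases and an explicit probability gamma that a virion, having
    irreversibly entered a cell, causes a productive infection. Provides the
    matching mean-field ordinary differential equation model, closed-form and
    root-found branching-process extinction probabilities, the negative
    binomial burst-size law and alternative burst-size models, Lambert-W
    final-size relations, and utilities to compare prophylactic antivirals
    that reduce the virus entry rate, the virus production rate, or the
    post-entry success probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
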