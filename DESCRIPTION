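Package: plasmidnets
Title: Stochastic Dynamics of Multihost-Multiplasmid Communities on Coupled
    Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exact stochastic (Gillespie) agent-based simulator of
    bacterial host-plasmid communities in which dynamics are constrained by
    two coupled ecological networks: a bipartite host-plasmid infection
    network deciding which plasmid can conjugate into which host, and a
    plasmid-plasmid compatibility network deciding which plasmids can
    co-reside in one cell. Subpopulations are host individuals sharing a
    binary plasmid profile; five event channels (growth, death, segregation
    loss, competition under a community-wide carrying capacity, and
    horizontal transfer weighted by an infection propensity tensor) drive
    the dynamics. The package ships canonical full/nested/modular infection
    and full/modular/hub compatibility motifs, a 3x3 factorial experiment
    driver with replicate ensembles, plasmid-cost sweeps, an
    empirically-motivated heterogeneous-trait scenario, community metrics
    (relative host abundance, plasmid prevalence, host composition,
    coexistence probability), a deterministic mean-field counterpart for
    validation, plain-text run storage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
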