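Package: hypoxmem
Title: Phenotype-Structured Simulation of Tumor Invasion Under Cyclic Hypoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator for a one-dimensional phenotype-structured
    PDE model of avascular tumor invasion under temporally fluctuating (cyclic)
    oxygen. Normoxic cells proliferate and switch to a migratory hypoxic
    phenotype structured by a continuous trait, the hypoxic-to-normoxic
    transition rate, whose drift toward lower values under sustained hypoxia
    encodes hypoxic memory. Hypoxic cells diffuse, move up extracellular-matrix
    gradients (haptotaxis) and degrade the matrix. The coupled system is solved
    by an explicit method-of-lines scheme with conservative first-order upwind
    advection in trait space and a CFL-limited forward-Euler step. Includes
    closed-form verification oracles for constant-oxygen regimes, the full
    observable suite (tumor boundary and volume, front hypoxic fraction,
    hitting times, phenotype distributions, strong-memory fractions,
    Jensen-Shannon divergence) and configuration-driven experiment runners for
    period, hypoxic-bias and memory-timescale sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
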