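Package: promec
Title: Coupled Pressure-Retarded Osmosis and Microbial Electrolysis Cell Process Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a batch pressure-retarded osmosis (PRO) unit hydraulically
    and energetically coupled to a two-chamber microbial electrolysis cell (MEC).
    The PRO side solves a time-dependent implicit water-flux model with internal
    and external concentration polarization, reverse salt flux, configurable
    hydraulic-pressure policies and osmotic-energy accounting. The MEC side
    integrates a batch two-population (exoelectrogen/methanogen) Monod model with
    an intracellular redox-mediator pool, Nernst electrode potentials,
    concentration overpotential, biomass-dependent internal resistance, and
    cumulative charge, energy and hydrogen bookkeeping. Includes scenario
    coupling (PRO effluents become MEC electrolytes, PRO energy caps MEC
    consumption), parameter calibration by relative root-mean-square error,
    scenario sweeps, YAML scenario configuration and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
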