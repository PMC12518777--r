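Package: ringflock
Title: Ring-Attractor Agents and the Emergence of Collective Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulations of cognitive agents whose movement
    decisions are generated by ring-attractor neural networks, under either
    a stochastic spin-system formulation (Metropolis single-spin dynamics on
    a Hopfield-type Hamiltonian) or a deterministic Amari-type neural-field
    formulation (Euler-discretized ring dynamics with tanh output).  Agents
    encode bearings egocentrically (the ring rotates with the heading),
    allocentrically (the ring is anchored to the world), or switch randomly
    between the two frames with continuous re-anchoring.  Supports
    single-agent target seeking, social coupling between agents (baseline,
    short-range repulsion, and distance-decay variants), periodic arenas,
    order-parameter analysis of collective motion (global and topological
    local order, mean pair distance, decision time), experiment presets, a
    configuration layer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
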