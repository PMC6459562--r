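Package: edgegames
Title: Evolutionary Multiplayer Games on Regular Graphs with Edge Diversity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for evolutionary multiplayer games
    on random regular graphs whose edges carry one of n types (social,
    genetic or geographic flavours of a tie). Provides the closed-form
    structure coefficients and the sigma rule that predict, under weak
    selection and death-birth updating, when one strategy is favoured over
    the other; the pair-approximation replicator equation for infinite
    populations; payoff constructors for edge-dependent pairwise games,
    diverse multiplayer games (volunteer's dilemmas, public goods games),
    weighted-graph games and division-of-labour threshold games; a compiled
    Monte Carlo death-birth simulator with an exact Markov-chain oracle on
    small graphs; and generators and readers for edge-typed regular graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
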