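Package: popgame
Title: Population Games with Instantaneous Habitat Choice
Version: 0.1.0
Authors@R:
    person("popgame", "developers", email = "popgame@example.org", role = c("aut", "cre"))
Description: Mean-field habitat-selection games coupled to slow population
    dynamics, instantiated on a behaviorally modified Rosenzweig-MacArthur
    predator-prey model in a continuous water column. The instantaneous game
    is solved as a Karush-Kuhn-Tucker complementarity system (semismooth
    Newton with the Fischer-Burmeister function), giving the mean-field Nash
    equilibrium (the simple ideal free distribution). On top of the game sit
    coupled population-Nash fixed points, forward-Euler transient dynamics
    with the game re-solved at every step, parameter sweeps over carrying
    capacity and predator competition, and diagnostics probing ideal-free
    structure, evolutionary stability and pseudomonotonicity of the game
    operator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
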