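Package: polymc
Title: Monte Carlo Simulation and Crystallographic Structure Analysis of
    Dense Polymer and Sphere Packings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Metropolis Monte Carlo simulation of chains and
    monomers interacting through hard-sphere, square-well/shoulder and
    Lennard-Jones potentials, under periodic boundaries, flat-wall, cylindrical
    or spherical confinement, and in the presence of immobile spherical or
    cylindrical nanofillers.  The move set includes configurational-bias local
    moves, chain-connectivity-altering bridging moves, identity-exchange moves
    for polymer/monomer blends, rigid cluster moves, volume moves and a
    compression protocol towards jammed states.  Local structure is classified
    per site against reference crystals (FCC, HCP, BCC, HEX and fivefold local
    symmetry in three dimensions; triangular, square, honeycomb and pentagonal
    in two) through a symmetry-element norm computed on Voronoi neighbor
    shells, yielding crystallinity fractions, ordered-cluster and Voronoi-cell
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
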