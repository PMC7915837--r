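Package: ipecdpd
Title: Dissipative Particle Dynamics of Interpolyelectrolyte Complex Micelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD) with explicit
    smeared-charge electrostatics for the co-assembly of oppositely charged
    diblock polyelectrolytes into core-shell nanoparticles with
    interpolyelectrolyte complex (IPEC) cores, and for the solubilization of
    rigid tetra-cationic porphyrin models into those cores.  Provides system
    builders (random and pre-aggregated initial states, porphyrin insertion,
    salt), a velocity-Verlet DPD integrator with rigid-body dynamics and
    cell-list neighbour search, Ewald electrostatics for exponentially smeared
    charges, and an observable stack: association-number statistics, aggregate
    weight distributions, solubilized fractions and radial density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
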