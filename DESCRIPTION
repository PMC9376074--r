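Package: cgdmd
Title: Event-Driven Coarse-Grained Molecular Dynamics of Cadherin Dimers
    and Anionic Nanoplastics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete molecular dynamics (DMD) at coarse-grained resolution
    for studying how anionic nanoplastic particles bind VE-cadherin EC1
    adhesion dimers and promote their force-induced dissociation. Provides
    step-function pair potentials (hard cores, square wells, discretized
    screened electrostatics, Go wells), an exact event-driven engine with
    an Anderson thermostat and constant-force steering, builders for
    Go-stabilized two-domain dimer models and bead-polymer nanoplastics
    (polystyrene and PMMA chemistries), replica binding and steered
    pulling campaign protocols, and the trajectory analysis stack:
    residue contact counting, binding-frequency profiles, first
    dissociation times, dimer angles, RMSF and radius of gyration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
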