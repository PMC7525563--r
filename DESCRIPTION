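Package: ppsucg
Title: Coarse-Grained Simulation of Dipolar Sulfone Homopolymer Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale coarse-grained molecular dynamics engine and
    analysis toolkit for dipolar bead-spring homopolymers in implicit
    DMSO/water solvent, modelling poly(propylene sulfone) self-assembly.
    Each monomer is a charge-neutral three-site unit (one positive backbone
    site, two negative oxygen sites) whose net dipole is calibrated in
    Debye; excluded volume uses the Weeks-Chandler-Andersen potential and
    electrostatics a truncated Coulomb sum screened by a uniform solvent
    dielectric. Langevin dynamics under piecewise-constant dielectric
    schedules encodes stepwise hydration histories; analysis operations
    include persistence length from bond-vector correlations, end-to-end
    distances, cluster formation analysis, gyration-tensor shape metrics,
    dipole moments of charge-neutral units, and surface charge enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
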