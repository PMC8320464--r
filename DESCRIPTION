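Package: maskflow
Title: Multiscale Simulation of Face-Mask Filtration and Sneeze Droplet Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates virtual nonwoven filter microstructures (spunbond and
    meltblown webs stacked into two-layer and three-layer mask media), solves
    creeping (Stokes) air flow through the voxelized webs to obtain pressure
    drop and Darcy permeability, computes size-resolved particle penetration by
    Lagrangian capture tracking, and couples the resulting mask model
    (penetration curve, permeability, calibrated face-seal leakage) to a
    Lagrangian sneeze-droplet dispersion simulation with Schiller-Naumann drag,
    Spalding/Ranz-Marshall evaporation and a parametric transient-jet plus
    ambient-wind carrier flow. Eight mask-wearing and wind scenarios are
    assembled end to end to predict maximum droplet transmission distances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
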