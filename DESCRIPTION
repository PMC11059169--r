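Package: activenematic
Title: Two-Field Active Nematic Modelling of Stress-Shape Misalignment in
    Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Continuum simulation and analysis of confluent cell monolayers in
    which the orientation of cell-generated contractile stress is decoupled
    from the cell-shape orientation. Two nematic order parameters (a shape
    tensor and a stress tensor) evolve under a shared free energy with an
    alignment coupling, advected and co-rotated by flows driven by the active
    stress, solved with a hybrid D2Q9 lattice-Boltzmann / finite-difference
    scheme. Includes the full measurement stack used on both simulations and
    experiment-like data: director-field construction from per-cell tables,
    principal-stress axes from monolayer stress grids, half-integer
    topological defect detection, misalignment (extensile/contractile)
    classification, interface-domain statistics, and spatial/temporal
    orientation and velocity correlation functions; a synthetic-data
    generator emulating monolayer experiments; and a pinned-defect
    relaxation scenario for passive (LP-9-like) monolayers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
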