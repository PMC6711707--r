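Package: insitu2d
Title: In Situ Two-Dimensional Receptor-Ligand Binding Kinetics and
    Companion Single-Cell Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of in situ two-dimensional (2D) receptor-ligand
    binding kinetics measured with the micropipette adhesion frequency
    assay: the probabilistic adhesion model, weighted nonlinear fitting of
    effective 2D affinity and off-rate, bootstrap standard errors, and a
    detection-limit path for unmeasurably weak interactions.  Companion
    analyses cover de-quenching (acceptor photobleaching) FRET efficiency
    with group comparison, recessive-model case-control association
    statistics on genotype count tables, and per-frame geometric
    descriptors of membrane-protein trajectories (helix tilt, ectodomain
    inclination, domain-bilayer distances, backbone dihedrals).  Seeded
    synthetic-data generators emulate every input, including an exact
    immigration-death stochastic bond simulator that serves as an
    independent oracle for the closed-form adhesion model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
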