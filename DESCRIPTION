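Package: qsprlm
Title: Linear QSPR/QSAR Modelling of Molecular Properties from SDF Molecule Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable engine for quantitative structure-property/activity
    relationship (QSPR/QSAR) modelling. Reads multi-record MDL SD (SDF) files
    with experimental property tags, computes a curated set of molecular
    descriptors (constitutional counts, hydrogen-bond donor/acceptor counts,
    rotatable bonds, aromaticity, Ertl topological polar surface area,
    Wildman-Crippen logP, additive van der Waals volume, radius of gyration,
    Gasteiger-Marsili charges over a Shrake-Rupley solvent-accessible surface
    for charged-partial-surface-area descriptors, and a generic SMARTS
    group-count family), fits linear property models by ordinary least squares
    with optional mean-centering, autoscaling (MCUV) or a stereographic
    projection of the property (Klopman-style solubility fitting), persists
    models as self-contained JSON, and evaluates predictions with r-squared,
    residual standard deviation, mean unsigned error and the largest signed
    deviation. Includes a seeded synthetic molecule-set generator with known
    ground-truth coefficients for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'charges.R'
    'chem-data.R'
    'chem-graph.R'
    'descriptors.R'
    'regression.R'
    'evaluation.R'
    'model-store.R'
    'ob-bridge.R'
    'sdf-io.R'
    'surface.R'
    'synthetic.R'
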