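Package: scfvfcdyn
Title: Structural Dynamics and Assay Analysis for scFv-Fc Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rigid-body domain motion of bivalent scFv-Fc antibody
    fusions from multi-frame structural ensembles: a pivot/center-point angular
    framework (inter-subunit XY-plane angles, contraction toward the hinge
    pivot, signed z-axis displacement), trajectory statistics (RMSD, per-domain
    RMSD, RMSF, radius of gyration, medoid representative frame, closest-frame
    search with Kabsch superposition), interchain hydrogen-bond and salt-bridge
    detection with a transparent stand-in contact potential, spatial
    conservation of the antigen-binding site by Fv alignment, and companion
    assay analyses (differential scanning fluorimetry melting temperatures by
    the first-derivative method, one-site saturation and four-parameter
    logistic binding fits).  Ships a synthetic-data module that builds Y-shaped
    toy scFv-Fc structures, scripted rigid-body trajectories, two-state melt
    curves and serial-dilution titrations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    signal
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
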