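Package: vpngrad
Title: Quantifying Molecular and Synaptic Gradients in Visual Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dorsoventral molecular and synaptic
    gradients within neuronal cell types, built around the Drosophila
    looming-detection circuit. Implements a volumetric HCR-FISH
    quantification pipeline (3D nucleus detection by Laplacian-of-Gaussian
    filtering, Voronoi partitioning, energy-minimizing threshold
    segmentation and per-nucleus puncta counting), within-cell-type
    expression-gradient statistics (QC, TP10K normalization, highly
    variable gene selection, PCA, covariate association and a
    continuity-versus-discreteness shuffle test), connectome
    synapse-count gradient regression, and physiology/behaviour metrics
    (looming-stimulus kinematics, dF/F, directional sensitivity index,
    bootstrap confidence intervals, takeoff-mode classification and
    elevation-gradient tests). Includes seeded synthetic-data generators
    with known ground truth for every input kind so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
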