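Package: bindscape
Title: Binding-Trajectory Analysis for Receptor-Ligand Association Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained and atomistic
    protein-protein association trajectories, built around the two-site
    (CRS1/CRS2) recognition model of chemokine receptor ligand binding.
    Provides collective variables (coordination number via a rational
    switching function, centre-of-mass and minimum distances, orientation
    angles), two-dimensional free-energy landscapes by Boltzmann inversion
    with basin detection, bound/unbound segmentation and engagement-order
    statistics (z-scored time-lag cross-correlation), GROMOS and
    density-peak conformational clustering, residue contact-frequency and
    difference maps, RMSD/RMSF/centre-of-mass fluctuation analyses,
    ensemble comparison in PCA space by centroid distance and
    Jensen-Shannon divergence, and missense-variant interface triage with
    contact-network centralities.  Ships synthetic-trajectory generators
    (pose-mixture and gated Langevin binders) with exact ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
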