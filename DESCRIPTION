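Package: fragdock
Title: Fragment-Map Free-Energy Docking, Binding-Site Hotspots, and
    Receptor Trajectory Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ligand binding-site analysis against voxelized grid
    free energy (GFE) fragment maps: the Boltzmann transform from fragment
    occupancy to free energy, DX-format grid input/output, ligand models with
    atom-class to map-type scoring rules, Metropolis Monte Carlo docking with
    simulated annealing and a cycle-level convergence protocol, global
    binding-site hotspot identification by two-round pose clustering ranked
    on average ligand GFE, and receptor trajectory metrics (Kabsch
    superposition RMSD, per-residue RMSF, center-of-mass distance traces,
    heavy-atom contact fractions, ionic-lock/NPxxY activation traces, moving
    averages, and linear mutual information correlation maps with thresholded
    inter-domain region detection). A synthetic-data module generates
    fragment maps with planted Gaussian wells, exclusion masks, schematic
    steroid-like ligands, a toy helical-bundle receptor, and multivariate
    Gaussian trajectories with closed-form RMSF and mutual-information ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
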