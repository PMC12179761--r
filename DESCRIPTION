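Package: remcs
Title: Solvation-Shell Microclusters from Molecular Dynamics and Weighted VCD Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased identification and statistical weighting of solute-solvent
    microclusters from molecular-dynamics trajectories. Extracts the solvent
    molecules inside an ellipsoid best fitting the solute (EMCS), reduces the
    cluster to the solvent molecules bound at preselected solute aggregation
    centers (rEMCS), analyses the resulting fixed-composition cluster
    trajectory by essential dynamics (PCA of roto-translationally fitted
    Cartesian coordinates), detects free-energy basins on the essential
    eigenvector projections and assigns statistical weights to representative
    conformations. Downstream utilities broaden per-conformer vibrational
    circular dichroism stick spectra with Gaussian line shapes, assemble
    probability-weighted composite spectra and compute a normalized
    spectrum-agreement RMSD. Includes a synthetic-fixture generator with known
    ground truth and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
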