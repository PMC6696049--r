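Package: twnr
Title: Topological Water Network Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for explicit-water molecular dynamics
    snapshots. Detects hydrogen-bonded 3- to 6-membered water rings
    (topological water networks, TWNs) using a pairwise Coulomb plus
    Lennard-Jones energy criterion, restricts analysis to a binding-site
    sphere, maps ring centers onto annotated regions of a reference ligand
    (head/linker/tail and the linker carbonyl position L'), aggregates
    occupancy percentages across frames, and scores ligand-TWN shape
    similarity on a boolean voxel grid to expose pharmacophoric hydration
    sites in a binding pocket. Includes a synthetic fixture generator that
    plants water rings with known ground truth so the full pipeline is
    testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
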