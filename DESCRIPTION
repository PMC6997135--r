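Package: trajkit
Title: Comparative Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of protein molecular dynamics
    ensembles stored as multi-model PDB files: Kabsch superposition with
    RMSD/RMSF/radius-of-gyration descriptors, RMSD-threshold conformational
    clustering with time-dependent cluster growth, residue contact maps with
    contact-similarity and reduction-rate statistics, geometric hydrogen-bond
    detection with occupancy, principal-component analysis with Boltzmann-
    inverted free-energy landscapes and basin extraction, HOLE-style pore
    radius profiling, radial distribution functions, and MM/PB(GB)SA binding
    free-energy bookkeeping with per-residue decomposition. Includes seeded
    synthetic-trajectory generators with analytic ground truth for testing
    every analysis stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
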