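Package: tcrmech
Title: Load-Dependent TCR-pMHC Trajectory Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of T-cell receptor
    (TCRalphabeta) complexes with peptide-MHC under mechanical load:
    interfacial contact detection and occupancy kinetics (hydrogen-bond and
    nonpolar criteria, rolling instantaneous occupancy, Hamming distance of
    initially persistent contacts), buried surface area by Shrake-Rupley
    sampling, rigid-body domain triads and a six-bead V-C bead-on-chain
    reduction with principal component analysis of interdomain motion,
    angle and distance order parameters (CDR3 distance, hinge angles,
    peptide tilt, transverse RMSF), and force estimation from harmonic
    positional restraints. Includes a synthetic-trajectory generator with
    known ground truth (prescribed rotational modes, scheduled contacts,
    Ornstein-Uhlenbeck restrained coordinates) so every analysis stage is
    testable by parameter recovery without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
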