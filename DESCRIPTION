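Package: scramblekit
Title: Quantitative Analysis of Phospholipid Scramblase Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying Ca2+-activated phospholipid scramblase
    (CaPLSase) function across three experimental modalities: per-cell
    scrambling kinetics (half-maximal time of Annexin V fluorescence
    accumulation) from time-lapse movies, patch-clamp analysis
    (current-voltage and conductance-voltage curves, reversal potentials,
    Goldman-Hodgkin-Katz permeability ratios, and free Ca2+ of
    EGTA-buffered solutions), and permeation profiling of particle
    trajectories (density and effective free-energy profiles along the
    membrane normal, 3D occupancy grids, and lipid externalization event
    detection). Seeded synthetic-data generators emulate each modality so
    that every analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
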