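Package: bnctplan
Title: Intensity-Modulated Irradiation Planning for Accelerator-Based BNCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treatment-planning toolkit for accelerator-based boron neutron
    capture therapy (BNCT) of superficial tumors using two overlapped
    irradiation fields. Enumerates the catalog of LiF-polyethylene intensity
    modulator aperture patterns on a 6x6 collimator grid, computes thermal and
    fast neutron flux and gamma dose-rate maps in a voxelized head phantom with
    a deterministic kernel-superposition transport engine, converts flux to
    RBE/CBE-weighted equivalent dose, prescribes irradiation time from normal
    tissue tolerance limits (skin 12 Gy-eq, brain 15 Gy-eq), and exhaustively
    searches pattern, modulator thickness and irradiation time ratio for the
    plan maximizing the minimum tumor dose. Reports dose-volume histograms,
    the homogeneity index and the surface thermal neutron flux uniformity
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
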