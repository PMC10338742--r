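Package: epomfit
Title: Effective Point of Measurement for Plane-Parallel Ionization
    Chambers in Clinical Electron Beams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines the effective point of measurement (EPOM) of
    plane-parallel ionization chambers from water-tank electron-beam
    depth scans.  Implements depth-scan reading, averaging and
    shape-preserving resampling; TRS-398 depth-wise ion-recombination
    (two-voltage method) and polarity corrections; ionization-to-dose
    conversion through the Burns water/air stopping-power-ratio
    parameterization in R50; and estimation of the EPOM shift by
    grid-search minimization of the root-mean-square deviation between
    the chamber curve and a reference percentage depth-dose curve.
    A synthetic-data generator produces reference curves and raw chamber
    scans with known ground truth so the whole pipeline is testable
    without measured data, and study-level aggregation reports
    chamber-type mean shifts and their energy dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
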