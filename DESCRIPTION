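Package: picslim
Title: Simulation, Reconstruction and Screening of SLIM Quantitative Phase Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial light interference microscopy (SLIM) image
    analysis: forward simulation of four phase-shifted interferograms and
    exact phase-map reconstruction, slide-scan planning with bilinear
    autofocus interpolation, tile stitching into mosaics, dry-mass
    densitometry with binary myelin masks, pooled phase histograms with
    overlap statistics, a synthetic fiber-texture tissue generator with
    two-factor (gestational size, diet) effect sizes, and a seeded
    classification stage with a two-dropout-layer head, confusion matrices
    and held-out-slide evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
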