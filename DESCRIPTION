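Package: plaquebeads
Title: Quantification of Fluorescent-Bead-Labeled Monocytes in Multiphoton Plaque Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated counting of 1-micron fluorescent beads carried by
    monocyte-derived cells in tiled multiphoton z-stacks of atherosclerotic
    plaques. Provides seeded synthetic scene and cohort generators with planted
    ground truth, sum-projection spot detection with physical diameter bounds
    and a calibratable brightness-above-background threshold, overlap-aware
    mosaic stitching and de-duplication, best-focus axial correction for 3D
    reconstructions, per-group statistics (SEM, fold change, percent reduction,
    one-tailed Student's t-test), and flow-cytometry-style gating to verify
    monocyte subset bead-labeling efficiency.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
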