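Package: dialyzerCT
Title: Counting Patent Fibers in Hemodialyzer Micro-CT Cross-Sections
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies fiber blocking (clotting) in hollow-fiber
    hemodialyzers from reconstructed micro-CT cross-sections of the
    potting region, where open fiber lumens appear as dark disks on a
    brighter polyurethane background. Provides dark-dot thresholding,
    bundle region-of-interest detection, distance-transform watershed
    separation of touching lumens, per-particle area, perimeter and
    circularity measurement, and a calibrated area-threshold patency
    classifier, together with slice- and threshold-reproducibility
    metrics and a surrogate-parameter regression panel. A synthetic
    phantom generator with exact per-fiber ground truth makes the whole
    pipeline testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
biocViews: Software, CellBasedAssays, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
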