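Package: arborfractal
Title: Fractal and Connectivity-Cost Analysis of 3D Dendritic Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3D neuromorphometric analysis of reconstructed
    dendritic arbors. Reads SWC reconstructions and Wavefront OBJ segment
    models, computes scalar morphometrics (total length, radius of gyration,
    convex-hull area and volume, fork and weave angles), multi-origin Sholl
    intersection and cumulative-mass profiles with mass-dimension fits,
    3D box-counting fractal dimension with automatic scaling-window
    selection, angle-scaling distortions of arbor geometry, orientation-
    averaged projection connectivity and tube-volume material cost, and the
    connectivity-cost optimization statistic with its peak dimension.
    Includes a synthetic generator of CA1-like basal arbors with group
    structure for calibration and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
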