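Package: camomatch
Title: Viewer-Corrected Pattern Metrics and Background-Matching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how well animal color patterns match the
    backgrounds available to them, as seen by an ecologically relevant
    observer. Implements a receptor-noise-limited (RNL) chain for cone-catch
    images (visual-acuity Gaussian filtering, chromatic and luminance
    just-noticeable-difference distances, RNL agglomerative segmentation,
    cluster, edge-intensity and secondary color-pattern statistics), assembly
    of cluster, edge and PCA-based visual-model component spaces, per-
    microhabitat optimal-background identification and interaction GLMs,
    convex-hull background-diversity measures, and range-wide lizard-by-
    background distance matrices compared with Hotelling's T-squared tests.
    A synthetic study generator emulating a multi-location, multi-clade
    lizard field design makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    car,
    emmeans,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
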