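Package: ooclust
Title: Quantitative Image Analysis of Chromosome Clustering in Oocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying chromosome clustering in mammalian
    oocytes from multi-channel 3D time-lapse fluorescence microscopy:
    chromatin focus segmentation, largest-pairwise-distance and convex-hull
    clustering kinetics, adaptive detection of nuclear envelope breakdown
    from a cytoplasmic dextran marker, nuclear-lamina-bounded particle image
    velocimetry of actin flow with circular statistics, and spot-to-surface
    colocalization with a mirrored-signal control. Includes a ground-truthed
    synthetic 3D(+t) microscopy generator so every stage of the pipeline can
    be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    mgcv,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
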