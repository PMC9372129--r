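Package: pcsgen
Title: Synthetic Oriented-Box Datasets of Protein Crystals in Suspension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates fully annotated synthetic grayscale training images of
    transparent protein crystals in suspension for oriented-object detectors.
    Crystal shapes are drawn from an unbiased statistical model (uniform aspect
    ratio and angle, reciprocal area density), realized by fitting projections
    of procedural convex 3D crystal meshes to the sampled minimum-area
    rectangles, rendered in a stylized bright-field look, and perturbed by a
    bespoke augmentation pipeline built on interference and Perlin noise
    layers. Also provides rotated-bounding-box average-precision evaluation
    with size-class breakdown, DOTA-style annotation export, and crystal-size-
    distribution analytics (quantile summaries, ECDFs, two-sample
    Kolmogorov-Smirnov tests, total-area trends) for detector output on
    photomicrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
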