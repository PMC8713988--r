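Package: zygoflow
Title: Morphokinetics and Cytoplasmic Flow Analysis for Zygote Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of bright-field time-lapse
    recordings of mammalian zygotes and early two-cell embryos. Extracts the
    cell (or zona pellucida) outline in every frame by Sobel edge detection
    and dynamic programming in polar coordinates, computes radial
    morphometrics (36 radii and 18 diameters at 10 degree steps about the
    centre of area, diameter standard deviation, axis ratios), detects
    rounder-distorted-rounder shape sequences and the first step of
    cytokinetic elongation, estimates cytoplasmic motion by multi-pass
    normalized cross-correlation particle image velocimetry, quantifies
    signed vorticity on masked vector fields with chi-squared sign
    comparisons between cells and half-cells, and builds kymographs along
    chosen diameters. A synthetic time-lapse generator with analytic ground
    truth (outlines, flow fields, injected shape events) supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
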