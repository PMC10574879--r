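Package: tubermorph
Title: Quantitative Morphometry of Seed-Coat Tubercles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of seed-coat tubercles from calibrated
    optical images. Fits endpoint-constrained Bezier curves to digitized
    tubercle outlines under chord-length parameterization, computes signed
    and absolute planar curvature profiles (reported in 1/micron x 1000),
    and derives the six standard tubercle variables: width at the base,
    height, slope (200 x height / width), maximum and mean absolute
    curvature, and their ratio. Includes an ImageJ-style line-graph
    extraction path from thresholded images, per-species summary statistics
    with one-way ANOVA, Tukey HSD and compact letter displays, Ward
    hierarchical clustering of species trait means with Newick export, a
    packaged reference dataset of 31 Silene species, and a fully seeded
    synthetic tubercle generator and image renderer for round-trip testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
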