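Package: cellcompass
Title: Morphodynamic Maps, Migration Persistence Statistics, and a
    Compass Model of Polarized Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of single-cell migration movies:
    threshold-based segmentation and centroid tracking with stage-jump
    correction, morphodynamic (cell-edge velocity) maps built from
    closed contours, trajectory persistence statistics (direction
    autocorrelation, persistence time, directionality ratio, circular
    axis-movement angles), trafficking maps of post-Golgi vesicle flow
    and their cross-correlation with edge protrusions, and a minimal
    stochastic "cell compass" model coupling protrusive events to an
    internal polarity axis.  The model produces phase diagrams of
    persistence time, protrusive unicity and axis-movement alignment
    over its two feedback parameters, which serve as look-up tables for
    inverse estimation of those parameters from measured observables.
    Synthetic-data generators (persistent-random-walk tracks, contour
    movies realizing a known edge-velocity map, lagged trafficking
    stacks, noisy blob images) provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
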