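Package: ringkinetics
Title: Quantitative Analysis of Contractile Ring Closure Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cytokinesis from point-annotated time-lapse
    microscopy of dividing cells, modelled on the analysis of C. elegans
    vulval precursor cell divisions. Fits circles through three-point
    annotations of the cell outline and contractile ring in the division
    plane, computes per-frame ring closure and furrow asymmetry, derives
    kinetics summaries (midpoint-aligned closure curves, 20-80% average
    speed, peak speed, duration), performs cell morphometrics and
    size-scaling regressions (ring breadth versus cell length, furrowing
    speed versus division-plane perimeter), and provides the unpaired
    t-test / one-way ANOVA layer used for group comparisons. A synthetic
    data module generates ground-truth sigmoidal closure trajectories with
    apically-polarized drift, jittered annotations, size-halving cell
    populations, and annulus-like division-plane image stacks, so every
    stage of the pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
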