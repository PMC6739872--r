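Package: scalegrad
Title: Spatial-Scale Selectivity Gradients in Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Block-design fMRI analysis of spatial-scale-selective brain
    activity: general linear model estimation with AR(2) serial-correlation
    correction and percent-signal-change scaling, voxelwise scale-tuning
    characterization via bounded Gaussian fits, detection of
    posterior-anterior gradients of preferred scale by a permutation test on
    the slope of the per-coordinate scale-preference profile, region-of-
    interest and network-overlap summaries, behavioral parametric modulation,
    and great-circle scaling analysis of geographic stimulus sets. Includes a
    synthetic-data module that generates randomized block paradigms,
    ground-truth tuning fields, simulated BOLD series with autoregressive
    noise, ratings tables and nested geographic stimulus sets, so the whole
    pipeline is testable end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    geosphere,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
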