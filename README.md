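# scalegrad

Analysis of spatial-scale-selective brain activity in block-design task
fMRI, for researchers studying how the cortex organizes processing of
environments from rooms to continents. The package implements the full
statistical pipeline — GLM estimation, voxelwise scale-tuning
characterization, and anatomical-gradient statistics — together with a
synthetic-data module that generates every input with known ground truth,
so the whole pipeline is testable end to end without scanner data.

## What it computes

Subjects compare distances between familiar items at six nested spatial
scales *s = 1..6* (room, building, neighborhood, city, country, continent)
in randomized 12.5 s blocks. Per voxel and subject, condition responses
are estimated by a GLM with HRF-convolved boxcar predictors, AR(2)
prewhitening and percent-signal-change scaling, giving betas
*β₁ … β₆*. The pipeline then:

1. **Selects scale-sensitive voxels** by single-factor repeated-measures
   ANOVA across the six betas over subjects,
   *F = MS_scale / MS_scale×subject* with df (5, 5(n−1)),
   Benjamini–Hochberg FDR across voxels (q < 0.01), and volumetric
   cluster filtering.
2. **Characterizes tuning** per voxel by a bounded Gaussian fit to the
   min-subtracted beta profile,
   *β(s) ≈ A·exp(−(s−c)²/2w²)*, keeping voxels with r² > 0.7; the fitted
   center *c* (clipped to [1,6]) is the preferred scale, with the argmax
   condition as an ordinal alternative.
3. **Tests anatomical gradients**: the mean preferred scale per coordinate
   along the posterior–anterior axis is regressed on the coordinate, and
   the slope is tested against a null built from 1000 shuffles of the
   per-coordinate scale-preference vector
   (*p = (1 + #{slope\* ≥ slope}) / (nPerm + 1)*), FDR-corrected across
   regions; a single-subject variant counts significant subjects.
4. **Summarizes regions**: per-scale ROI betas with across-subject SEs,
   event-related averages over the 10 volumes after block onset, and
   percent overlap with a network parcellation.
5. **Relates behavior and stimulus geography**: per-subject correlations
   of z-transformed ratings with scale, one-way ANOVA with Tukey–Kramer
   post-hocs, parametric-modulation regressors, and the log-linear
   relation between scale and environment size from Haversine great-circle
   distances.

## Worked example

A scaled-down synthetic study (4 subjects, one 200-volume run each,
10×16×10 voxel grid) with a true posterior→anterior gradient in one region
and flat-tuned control region:

```r
library(scalegrad)

cfg <- defaultPipelineConfig()
cfg$n_subjects <- 4
cfg$grid       <- c(10L, 16L, 10L)
cfg$n_runs     <- 1
cfg$n_perm     <- 200

report <- runFullPipeline(cfg)
report$stages$gradient
#>     region        slope           p           q significant
#> 1 gradient 0.3285803953 0.004975124 0.009950249        TRUE
#> 2  control 0.0004676015 0.517412935 0.517412935       FALSE
```

The `gradient` region — where the generator placed tuning centers running
from scale 1 posteriorly to scale 6 anteriorly — shows a positive slope
(0.33 scale units per voxel coordinate) whose one-sided permutation p,
FDR-adjusted across the two regions, is significant; the control region,
tuned everywhere to the same scale, is not. `report$stages$selectivity`
records that 195 of 576 analysis-mask voxels passed the ANOVA+FDR gate,
and `report$stages$geo$r2` gives the log-linear fit of stimulus-set size
on scale (r² ≈ 0.99 with the default dispersions).

Individual stages are plain functions on S4 objects if you want them
à la carte — e.g. `fitGaussianTuning(betas)` for one voxel's 6-vector, or
`permutationTestSlope(profile, nPerm = 1000, seed = 1)` for one region's
axis profile. A thin CLI covering the same stages is in `exec/scalegrad`.

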