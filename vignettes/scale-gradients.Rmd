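---
title: "Methods: spatial-scale selectivity gradients in task fMRI"
author: "scalegrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-scale selectivity gradients in task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalegrad)
```

# The scientific question and the analysis model

Human spatial cognition spans environments from a single room to a whole
continent. A block-design fMRI experiment can probe whether the same
cortical system processes all of these spatial scales by asking subjects to
compare distances between personally familiar items at six nested scales
(room, building, neighborhood, city, country, continent), presented in
randomized 12.5 s blocks (one 2.5 s target plus four 2.5 s paired
comparisons) separated by 7.5 s fixation, with four blocks per scale per run
at TR 2.5 s. The analysis this package implements asks two things of such
data:

1. **Which voxels care about spatial scale at all?** Per voxel, a
   single-factor repeated-measures ANOVA across the six condition betas
   (across subjects), corrected voxelwise by Benjamini-Hochberg FDR.
2. **How is scale preference organized anatomically?** Each selected
   voxel's six-beta profile is summarized by a bounded Gaussian tuning fit
   and by its argmax condition; the per-coordinate mean preferred scale
   along the posterior-anterior (Y) axis is then tested for a linear
   increase with a permutation test on the fitted slope.

The package is organized Bioconductor-style: S4 classes with validity
methods hold the central objects (`Paradigm`, `TuningField`, `NoiseSpec`,
`ScaleBetaMap`, `VoxelTuning`, `AxisProfile`, `GradientTestResult`), and
camelCase functions operate on them.

# GLM estimation

Each scale's predictor is a boxcar spanning the full 12.5 s block,
convolved with a canonical double-gamma HRF and sampled at volume onsets.
The HRF is `dgamma(t, 6, 1) - dgamma(t, 16, 1)/6`, rescaled analytically to
unit integral, so its positive lobe peaks 5 s after onset and a sustained
block regressor plateaus near 1. The original analysis names only a
"canonical" HRF; the double-gamma with delay 6 s, undershoot 16 s and ratio
1/6 is the community default, and all three parameters are exposed in
`hrfKernel()`. Convolution happens on a 0.1 s grid as a plain Riemann sum,
which a brute-force oracle can reproduce to 1e-8; the TR must be a multiple
of the fine grid step.

Voxel time series are scaled to percent signal change,
`100 (x - mean) / mean`, with voxels at or below the intensity threshold
(100 in raw scanner units) excluded rather than erroring. Serial
correlations are handled by a two-pass AR(2) procedure: OLS residuals,
Yule-Walker AR(2) coefficients estimated within runs, prewhitening of both
data and design (dropping the first two volumes of each run), and
re-estimation. The source analysis names AR(2) but not the estimator;
per-voxel Yule-Walker is the default here and a pooled variant (median
coefficients across voxels, one shared whitening) is provided for speed —
the demo pipeline uses the pooled variant. Sample Yule-Walker estimates are
stationary by construction in well-behaved data; the rare boundary case is
shrunk back into the stationarity triangle.

Group summaries are classical random effects: across-subject mean, SE and
one-sample t per voxel and condition, with `t` reported as missing (never
infinite) where the SE is zero. Contrasts (e.g. spatial task versus lexical
control) are paired across-subject t-tests on a weighted combination of
condition betas.

Parametric modulation regressors take a rating measure, z-transform it
within subject (sample n-1 SD; a zero-variance vector yields zeros and a
flag), assign each block its location's or scale's z-score, scale the
boxcar, convolve, and mean-center. Each modulator is meant to run in its
own GLM; no orthogonalization against the task regressors is applied.
Optional high-pass filtering is implemented as cosine/sine pairs for the
first k Fourier cycles per run, off by default for synthetic data (the
simulated drift is a single low-frequency cosine, and the percent-signal-
change transform plus per-run intercepts already absorb most of it).

# Tuning characterization

The six condition betas of a voxel are first shifted by subtracting their
minimum, then fitted with `A * exp(-(s - c)^2 / (2 w^2))` at `s = 1..6`
under bounds A in [0, 100], c in [-100, 100], w in (0, 100]. The optimizer
is bounded L-BFGS-B least squares with multi-start: the center is started
at each of s = 1..6, which reliably finds boundary-attracted optima for
monotone profiles (an increasing 6-vector fits with c >= 6). Goodness of
fit is `r2 = 1 - SS_res / SS_tot` on the min-subtracted vector — the
original report does not define its r-squared, so this definition is stated
explicitly to make the 0.7 gate reproducible. A flat vector has zero
SS_tot, an undefined r2 and fails the gate. The continuous preferred scale
is the fitted center clipped to [1, 6]; the ordinal alternative is the
argmax condition, with ties broken toward the smallest index (the source is
silent; lowest-index is documented and tested).

Cluster filtering is volumetric — connected components (6-connectivity by
default, 18/26 available) below 5 voxels are removed. The published
threshold of 15 mm^2 applies to surface maps, which this package does not
render; 5 voxels at 3 mm isotropic is the volumetric default and is
configurable. The repeated-measures ANOVA uses the uncorrected F with df
(5, 5(n-1)); sphericity correction is not applied, matching the source's
silence on the point, and the FDR correction runs over the configured
analysis mask.

# Gradient statistics

For one region and one axis, the profile is the mean preferred scale at
each coordinate slice containing at least one gated voxel (empty slices
are omitted, not zero-filled). The observed statistic is the slope of the
unweighted least-squares line of mean preferred scale on coordinate —
unweighted because each coordinate enters as one averaged observation; a
voxel-count-weighted option exists. The null distribution shuffles the
per-coordinate mean vector itself (the "scale preference vector"), not the
underlying voxels. The sampled p-value uses the add-one rule
`p = (1 + #(null >= observed)) / (nPerm + 1)`, which avoids p = 0 and keeps
p >= 1/(nPerm+1); profiles of up to 8 coordinates can be tested exactly by
full enumeration, where the monotone 6-point profile gives p = 1/720.
The test is one-sided for an increase toward anterior by default, matching
the directional hypothesis; two-sided is available. P-values across
regions are BH-adjusted. The hippocampal long axis is handled identically —
the same Y-axis machinery with a hippocampus mask.

The single-subject variant refits the Gaussian tuning on each subject's own
betas inside the group-defined region, tests each subject's profile, and
BH-adjusts across subjects; subjects with no gated voxels are flagged and
counted non-significant.

# The synthetic-data generator

Every downstream stage is testable without any scanner data because the
generator produces inputs with the statistical structure the analysis
assumes:

* **Paradigms** reproduce the block design: 12.5 s blocks, 7.5 s fixation,
  randomized order, equal blocks per scale per run, two locations per
  scale. The default acquisition (24 blocks, TR 2.5 s) yields 200 volumes
  per run.
* **Tuning fields** place true Gaussian tuning parameters on a 3D grid
  (default 20 x 40 x 20 voxels at 3 mm — the functional resolution of the
  emulated acquisition, at desk scale). Inside the gradient mask the true
  center is `intercept + slope * coordinate` plus Gaussian jitter, clipped
  to [1, 6]; the default slope spans centers 1 to 6 across the mask.
* **BOLD simulation** injects each voxel's per-scale response — the same
  parametric Gaussian the fitter assumes, making parameter recovery
  well-posed — as a *zero-mean* modulation of the convolved predictors
  around a positive baseline. Because the voxel mean then equals the
  baseline, injected amplitudes are exact in percent-signal-change units
  after scaling, and the zero-noise closed loop through the GLM recovers
  them to floating-point accuracy. Noise is AR(2) (default coefficients
  0.3/0.2, mirroring the AR(2) correction the fitter applies) plus a single
  demeaned cosine drift; defaults (innovation SD 1% of baseline, drift
  0.5% at 128 s) are ordinary task-fMRI magnitudes.
* **Geographic stimulus sets** scatter items around random location centers
  with per-scale dispersions of 0.5, 10, 500 and 5000 km (neighborhood to
  continent), using great-circle destination points so continent-scale sets
  remain valid on the sphere. Mean log pairwise distance then grows close
  to linearly in scale.
* **Ratings** are drawn so each measure's correlation with scale matches a
  target — defaults are the reported values (familiarity -0.72, difficulty
  0.39, first-person -0.81, third-person +0.80). For location-level
  measures the noise is inflated by sqrt(2) so the target holds for the
  analyzed quantity (per-subject scale means over the two locations per
  scale). A target of +/-1 produces perfectly ordered ratings.

What the generator does *not* emulate: motion and physiological artifacts,
spatial autocorrelation of noise, realistic anatomy or inter-regional
heterogeneity, multi-band acquisition. Passing tests therefore demonstrate
the statistical machinery's correctness and calibration, not robustness to
those real-data complications — the pipeline consumes preprocessed,
MNI-normalized volumes and assumes artifact handling happened upstream.

Since inter-subject variability of gradient geometry is not reported
anywhere usable, the demo exposes a per-subject multiplicative slope jitter
(default SD 10%) rather than fixing one value.

# Numerical choices and degenerate inputs

* Generators are pure functions of their seed (the global RNG state is
  saved and restored), so every table the pipeline writes is byte-identical
  across reruns with the same configuration.
* Width in the Gaussian fit is bounded below at 1e-3 (not 0) to keep the
  exponent finite.
* Voxels whose mean intensity fails the threshold are carried as NA through
  the GLM, not dropped from the grid.
* A constant axis profile returns slope 0 and p = 1 without error; an
  all-equal ANOVA cell table returns F = 0, p = 1.
* Zero great-circle distances (co-located items) are retained by the
  distance computation but excluded, with a count, from the log-linear fit.
  Per-scale aggregation uses the mean of log distances by default
  (log-of-mean and per-pair fits are options); with only two scales the
  fit is flagged as underdetermined.
* The Earth radius defaults to the 6371 km mean radius and is configurable.

# Problem sizes

The bundled demo (`inst/extdata/demo_config.yaml`) simulates 8 subjects,
2 runs of 200 volumes on the 20 x 40 x 20 grid, tests gradients with 1000
permutations, and completes in about a minute on one CPU; the calibration
studies in the test suite use 100-500 simulated datasets per check and
5000-voxel null fields. These sizes were chosen as the smallest that make
the calibration checks statistically meaningful.

# Known limitations

* Surface-based statistics (the published cluster threshold's native
  space) are out of scope; cluster extent is volumetric.
* The axis is a straight voxel-grid axis; curved or geodesic axis
  parameterizations (e.g. of the hippocampus) are not implemented.
* Masks and parcellations are accepted as label volumes on the analysis
  grid; the published scene-area masks and 7-network parcellation are not
  redistributed, and the demo uses synthetic stand-ins (a two-label
  posterior/anterior parcellation).
* The lexical-control contrast machinery is exercised with synthetic
  control blocks; no linguistic stimulus modeling is attempted.
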