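#' @import methods
NULL

SCALE_LABELS <- c("room", "building", "neighborhood", "city", "country", "continent")
N_SCALES <- 6L

#' Block-design experimental paradigm
#'
#' Timing table for a randomized block design: each block presents one
#' location at one of six nested spatial scales (room ... continent) and is
#' followed by fixation. Invariants enforced by the validity method: onsets
#' strictly increasing within a run, blocks contained in the acquisition
#' window, and an equal number of spatial-task blocks per scale within each
#' run.
#'
#' @slot blocks data.frame with columns `run`, `onset`, `duration`, `scale`
#'   (1-6), `location`, `task` ("spatial" or "lexical"); times in seconds.
#' @slot trSeconds repetition time in seconds.
#' @slot volumesPerRun number of volumes acquired per run.
#' @slot nRuns number of runs.
#' @export
setClass("Paradigm",
  representation(blocks = "data.frame", trSeconds = "numeric",
                 volumesPerRun = "integer", nRuns = "integer"))

setValidity("Paradigm", function(object) {
  b <- object@blocks
  need <- c("run", "onset", "duration", "scale", "location", "task")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns:", paste(need, collapse = ", ")))
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  runLen <- object@volumesPerRun * object@trSeconds
  for (r in unique(b$run)) {
    br <- b[b$run == r, ]
    if (is.unsorted(br$onset, strictly = TRUE))
      return(sprintf("onsets not strictly increasing in run %d", r))
    if (any(br$onset + br$duration > runLen + 1e-9))
      return(sprintf("block outside acquisition window in run %d", r))
    sp <- br[br$task == "spatial", ]
    if (nrow(sp) > 0L) {
      counts <- tabulate(sp$scale, nbins = N_SCALES)
      if (length(unique(counts[counts > 0L])) != 1L)
        return(sprintf("unequal per-scale block counts in run %d", r))
    }
  }
  if (!all(b$scale %in% 1:6)) return("scale indices must be in 1..6")
  TRUE
})

#' Ground-truth voxel tuning field
#'
#' Per-voxel true Gaussian-tuning parameters on a 3D grid. Inside the
#' gradient mask the true tuning center is an affine function of the
#' coordinate along `axis` (plus bounded jitter, clipped to [1, 6]); outside
#' the mask voxels may be untuned (amplitude 0).
#'
#' @slot dim grid shape (x, y, z) in voxels.
#' @slot voxelSizeMm isotropic voxel edge length, mm.
#' @slot amplitude,center,width 3D arrays of true tuning parameters
#'   (amplitude in percent-signal-change units, center/width on the 1-6
#'   scale axis).
#' @slot mask logical 3D array marking the gradient region.
#' @slot axis axis index (1 = x, 2 = y, 3 = z) along which the center varies.
#' @slot slope true gradient slope, scale units per mm.
#' @slot intercept true center at axis coordinate 0 mm.
#' @export
setClass("TuningField",
  representation(dim = "integer", voxelSizeMm = "numeric",
                 amplitude = "array", center = "array", width = "array",
                 mask = "array", axis = "integer", slope = "numeric",
                 intercept = "numeric"))

setValidity("TuningField", function(object) {
  d <- object@dim
  if (length(d) != 3L || any(d < 1L)) return("dim must be a positive length-3 integer")
  for (s in c("amplitude", "center", "width", "mask"))
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("slot '%s' does not match grid dim", s))
  if (!object@axis %in% 1:3) return("axis must be 1, 2 or 3")
  if (object@voxelSizeMm <= 0) return("voxelSizeMm must be positive")
  if (!any(object@mask)) return("gradient mask is empty")
  cen <- object@center[object@mask]
  if (any(cen < 1 - 1e-9 | cen > 6 + 1e-9))
    return("true centers inside the mask must lie in [1, 6]")
  TRUE
})

#' Noise model for simulated BOLD series
#'
#' AR(p<=2) temporal noise plus a single low-frequency cosine drift on top of
#' a positive baseline intensity. The AR polynomial must be stationary.
#'
#' @slot ar autoregressive coefficients (length 0-2).
#' @slot innovationSd innovation standard deviation (scanner units).
#' @slot driftAmplitude,driftPeriodSeconds cosine drift parameters.
#' @slot baseline baseline intensity (> 0, scanner units).
#' @export
setClass("NoiseSpec",
  representation(ar = "numeric", innovationSd = "numeric",
                 driftAmplitude = "numeric", driftPeriodSeconds = "numeric",
                 baseline = "numeric"))

arIsStationary <- function(a) {
  if (length(a) == 0L) return(TRUE)
  if (length(a) == 1L) return(abs(a) < 1)
  # AR(2) stationarity triangle
  abs(a[2]) < 1 && a[1] + a[2] < 1 && a[2] - a[1] < 1
}

setValidity("NoiseSpec", function(object) {
  if (length(object@ar) > 2L) return("AR order must be <= 2")
  if (!arIsStationary(object@ar)) return("AR coefficients are not stationary")
  if (object@baseline <= 0) return("baseline intensity must be > 0")
  if (object@innovationSd < 0 || object@driftAmplitude < 0)
    return("standard deviations and amplitudes must be non-negative")
  if (object@driftPeriodSeconds <= 0) return("drift period must be positive")
  TRUE
})

#' Geographic stimulus set
#'
#' Latitude/longitude of stimulus items, nested by spatial scale
#' (3 = neighborhood ... 6 = continent; rooms and buildings have no
#' geographic coordinates) and location.
#'
#' @slot entries data.frame with columns `scale`, `location`, `item`,
#'   `lat`, `lon` (decimal degrees).
#' @export
setClass("GeoStimulusSet", representation(entries = "data.frame"))

setValidity("GeoStimulusSet", function(object) {
  e <- object@entries
  need <- c("scale", "location", "item", "lat", "lon")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (any(e$lat < -90 | e$lat > 90)) return("latitude outside [-90, 90]")
  if (any(e$lon < -180 | e$lon > 180)) return("longitude outside [-180, 180]")
  if (!all(e$scale %in% 3:6)) return("geographic scales are 3..6")
  n <- table(paste(e$scale, e$location))
  if (any(n < 2L)) return("every location needs >= 2 items")
  TRUE
})

#' Subject ratings table
#'
#' Post-scan behavioral ratings: per subject x location (familiarity,
#' emotional significance, judgment difficulty, each 1-7) and per subject x
#' scale (first-person and third-person perspective-taking, map-strategy
#' use).
#'
#' @slot locationRatings data.frame: `subject`, `location`, `scale`,
#'   `familiarity`, `emotion`, `difficulty`.
#' @slot scaleRatings data.frame: `subject`, `scale`, `firstPerson`,
#'   `thirdPerson`, `mapStrategy`.
#' @slot bounds numeric length-2 rating bounds (default 1, 7).
#' @export
setClass("RatingsTable",
  representation(locationRatings = "data.frame", scaleRatings = "data.frame",
                 bounds = "numeric"))

setValidity("RatingsTable", function(object) {
  b <- object@bounds
  if (length(b) != 2L || b[1] >= b[2]) return("bounds must be (lo, hi)")
  vals <- c(object@locationRatings$familiarity, object@locationRatings$emotion,
            object@locationRatings$difficulty, object@scaleRatings$firstPerson,
            object@scaleRatings$thirdPerson, object@scaleRatings$mapStrategy)
  if (any(vals < b[1] - 1e-9 | vals > b[2] + 1e-9, na.rm = TRUE))
    return("ratings outside declared bounds")
  TRUE
})

#' GLM design matrix
#'
#' Volumes x predictors matrix: HRF-convolved boxcar columns for the six
#' scale conditions (plus optional control-task, modulation and nuisance
#' columns) and exactly one intercept column per run.
#'
#' @slot matrix numeric matrix, one row per acquired volume.
#' @slot runIndex run membership of each row.
#' @slot trSeconds repetition time in seconds.
#' @slot taskColumns names of the condition columns.
#' @export
setClass("DesignMatrix",
  representation(matrix = "matrix", runIndex = "integer",
                 trSeconds = "numeric", taskColumns = "character"))

setValidity("DesignMatrix", function(object) {
  X <- object@matrix
  if (nrow(X) != length(object@runIndex))
    return("runIndex length must equal number of rows")
  if (is.null(colnames(X))) return("design columns must be labeled")
  for (r in unique(object@runIndex)) {
    ic <- grep("^intercept_run", colnames(X))
    sub <- X[object@runIndex == r, ic, drop = FALSE]
    if (sum(colSums(sub != 0) > 0) != 1L)
      return(sprintf("run %d must have exactly one intercept column", r))
  }
  TRUE
})

#' Per-voxel GLM fit
#'
#' Condition betas (percent-signal-change units), standard errors, AR(2)
#' coefficient estimates and residual degrees of freedom from the two-pass
#' prewhitened fit.
#'
#' @slot betas,se voxels x columns matrices.
#' @slot arCoefficients voxels x 2 matrix of AR coefficient estimates.
#' @slot df residual degrees of freedom (volumes used - rank of design).
#' @slot columns design column labels.
#' @export
setClass("GlmFit",
  representation(betas = "matrix", se = "matrix", arCoefficients = "matrix",
                 df = "numeric", columns = "character"))

#' Per-subject map of condition betas on a voxel grid
#'
#' @slot betas 4D array (x, y, z, 6 scales), percent-signal-change units.
#' @slot voxelSizeMm isotropic voxel size, mm.
#' @export
setClass("ScaleBetaMap",
  representation(betas = "array", voxelSizeMm = "numeric"))

setValidity("ScaleBetaMap", function(object) {
  d <- dim(object@betas)
  if (length(d) != 4L || d[4] != N_SCALES)
    return("betas must be a 4D array with 6 condition planes")
  TRUE
})

#' Group random-effects summary of condition betas
#'
#' @slot mean,se,t 4D arrays (x, y, z, condition): across-subject mean,
#'   standard error, and one-sample t (NA where SE is 0).
#' @slot n number of contributing subjects.
#' @export
setClass("GroupBetaMap",
  representation(mean = "array", se = "array", t = "array", n = "integer"))

#' Voxelwise tuning-fit table
#'
#' One row per fitted voxel: bounded Gaussian tuning fit to the six condition
#' betas (after min-subtraction), goodness of fit, continuous peak scale and
#' ordinal max scale.
#'
#' @slot fits data.frame: `voxel` (linear index), `x`, `y`, `z`, `amplitude`,
#'   `center`, `width`, `r2`, `peakScale`, `maxScale`, `passesGate`.
#' @slot dim grid shape.
#' @slot gate the r-squared gate applied (default 0.7).
#' @export
setClass("VoxelTuning",
  representation(fits = "data.frame", dim = "integer", gate = "numeric"))

#' Scale-sensitivity selection mask
#'
#' Voxelwise repeated-measures ANOVA statistics with BH-FDR selection and
#' connected-component cluster labels.
#'
#' @slot F,p,q 3D arrays of the ANOVA F statistic, p-value and FDR-adjusted
#'   q-value (NA outside the analysis mask).
#' @slot selected logical 3D array (q < alpha).
#' @slot cluster integer 3D array of cluster ids (0 = unselected).
#' @slot alpha FDR level used for selection.
#' @export
setClass("SelectivityMask",
  representation(F = "array", p = "array", q = "array", selected = "array",
                 cluster = "array", alpha = "numeric"))

#' Preferred-scale profile along an anatomical axis
#'
#' Per-coordinate mean preferred scale within one region, ordered from
#' posterior to anterior.
#'
#' @slot region region label.
#' @slot axis axis index (1 = x, 2 = y, 3 = z).
#' @slot method "peak" (Gaussian-fit center) or "max" (argmax condition).
#' @slot coordinates strictly increasing axis coordinates with >= 1
#'   contributing voxel.
#' @slot meanScale per-coordinate mean preferred scale.
#' @slot nVoxels per-coordinate contributing voxel count.
#' @export
setClass("AxisProfile",
  representation(region = "character", axis = "integer", method = "character",
                 coordinates = "numeric", meanScale = "numeric",
                 nVoxels = "integer"))

setValidity("AxisProfile", function(object) {
  if (is.unsorted(object@coordinates, strictly = TRUE))
    return("coordinates must be strictly increasing")
  n <- length(object@coordinates)
  if (length(object@meanScale) != n || length(object@nVoxels) != n)
    return("coordinates, meanScale and nVoxels must have equal length")
  if (any(object@nVoxels < 1L)) return("each coordinate needs >= 1 voxel")
  TRUE
})

#' Permutation test result for a gradient slope
#'
#' @slot region region label.
#' @slot slope,intercept least-squares line of mean preferred scale on axis
#'   coordinate.
#' @slot nPerm number of permutations (or number enumerated when exact).
#' @slot p permutation p-value (add-one rule for sampled permutations).
#' @slot q FDR-adjusted p across regions (NA until adjusted).
#' @slot sided "one" (increase) or "two".
#' @slot exact TRUE when all permutations were enumerated.
#' @slot nCoordinates number of profile coordinates tested.
#' @export
setClass("GradientTestResult",
  representation(region = "character", slope = "numeric", intercept = "numeric",
                 nPerm = "integer", p = "numeric", q = "numeric",
                 sided = "character", exact = "logical",
                 nCoordinates = "integer"))

setValidity("GradientTestResult", function(object) {
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  TRUE
})
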