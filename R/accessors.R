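#' Accessors for scalegrad S4 objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object a scalegrad S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blocks", function(object) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setMethod("blocks", "Paradigm", function(object) object@blocks)

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setMethod("trSeconds", "Paradigm", function(object) object@trSeconds)

#' @rdname accessors
#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))
#' @rdname accessors
#' @export
setMethod("nRuns", "Paradigm", function(object) object@nRuns)

#' @rdname accessors
#' @export
setGeneric("volumesPerRun", function(object) standardGeneric("volumesPerRun"))
#' @rdname accessors
#' @export
setMethod("volumesPerRun", "Paradigm", function(object) object@volumesPerRun)

#' @rdname accessors
#' @export
setGeneric("betaArray", function(object) standardGeneric("betaArray"))
#' @rdname accessors
#' @export
setMethod("betaArray", "ScaleBetaMap", function(object) object@betas)
#' @rdname accessors
#' @export
setMethod("betaArray", "GroupBetaMap", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("tuningFits", function(object) standardGeneric("tuningFits"))
#' @rdname accessors
#' @export
setMethod("tuningFits", "VoxelTuning", function(object) object@fits)

#' @rdname accessors
#' @export
setGeneric("geoEntries", function(object) standardGeneric("geoEntries"))
#' @rdname accessors
#' @export
setMethod("geoEntries", "GeoStimulusSet", function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("trueCenters", function(object) standardGeneric("trueCenters"))
#' @rdname accessors
#' @export
setMethod("trueCenters", "TuningField", function(object) object@center)

#' @rdname accessors
#' @export
setGeneric("gradientMask", function(object) standardGeneric("gradientMask"))
#' @rdname accessors
#' @export
setMethod("gradientMask", "TuningField", function(object) object@mask)

setMethod("show", "Paradigm", function(object) {
  b <- object@blocks
  cat(sprintf("Paradigm: %d run(s), %d blocks, TR %.2f s, %d volumes/run\n",
              object@nRuns, nrow(b), object@trSeconds, object@volumesPerRun))
  cat(sprintf("  tasks: %s; scales 1-6 balanced within run\n",
              paste(unique(b$task), collapse = ", ")))
})

setMethod("show", "TuningField", function(object) {
  cat(sprintf("TuningField: %s grid at %.1f mm, axis %d, slope %.4f scale/mm\n",
              paste(object@dim, collapse = "x"), object@voxelSizeMm,
              object@axis, object@slope))
  cat(sprintf("  %d voxels in gradient mask\n", sum(object@mask)))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: AR(%d) [%s], innovation sd %.3g, drift %.3g/%.0f s, baseline %.3g\n",
              length(object@ar), paste(signif(object@ar, 3), collapse = ", "),
              object@innovationSd, object@driftAmplitude,
              object@driftPeriodSeconds, object@baseline))
})

setMethod("show", "VoxelTuning", function(object) {
  f <- object@fits
  cat(sprintf("VoxelTuning: %d voxels fitted, %d pass r2 > %.2f gate\n",
              nrow(f), sum(f$passesGate, na.rm = TRUE), object@gate))
})

setMethod("show", "AxisProfile", function(object) {
  cat(sprintf("AxisProfile [%s, axis %d, method %s]: %d coordinates, mean scale %.2f-%.2f\n",
              object@region, object@axis, object@method,
              length(object@coordinates),
              min(object@meanScale), max(object@meanScale)))
})

setMethod("show", "GradientTestResult", function(object) {
  cat(sprintf("GradientTestResult [%s]: slope %.4f, %s-sided p = %.4g (%s%d perms)%s\n",
              object@region, object@slope, object@sided, object@p,
              if (object@exact) "exact, " else "", object@nPerm,
              if (is.na(object@q)) "" else sprintf(", q = %.4g", object@q)))
})

setMethod("show", "GroupBetaMap", function(object) {
  cat(sprintf("GroupBetaMap: %s grid, %d subjects\n",
              paste(dim(object@mean)[1:3], collapse = "x"), object@n))
})

setMethod("show", "SelectivityMask", function(object) {
  cat(sprintf("SelectivityMask: %d voxels tested, %d selected at q < %.3g, %d cluster(s)\n",
              sum(!is.na(object@p)), sum(object@selected, na.rm = TRUE),
              object@alpha, max(object@cluster)))
})
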