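# All generators are pure functions of their seed: the global RNG state is
# saved and restored around every draw.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a randomized six-scale block paradigm
#'
#' Emulates the study design: blocks of 12.5 s (2.5 s target + four 2.5 s
#' proximity comparisons) each followed by 7.5 s fixation, in randomized
#' order, with an equal number of blocks per spatial scale within each run.
#' Each scale has two locations; a run's blocks at one scale alternate
#' between them.
#'
#' @param nRuns number of runs (study default 4).
#' @param blocksPerRun blocks per run, divisible by 6 (study default 24, i.e.
#'   4 blocks per scale, 2 per location).
#' @param tr repetition time in seconds (study default 2.5).
#' @param seed integer RNG seed; the paradigm is a pure function of it.
#' @param volumesPerRun volumes acquired per run; default covers all blocks
#'   plus 20 s of trailing rest (200 volumes for the default design).
#' @param blockDuration,fixation block and fixation durations in seconds.
#' @return a [Paradigm].
#' @examples
#' p <- generateParadigm(4, 24, 2.5, seed = 1)
#' table(blocks(p)$scale) / nRuns(p)  # 4 blocks per scale per run
#' @export
generateParadigm <- function(nRuns = 4, blocksPerRun = 24, tr = 2.5, seed = 1,
                             volumesPerRun = NULL, blockDuration = 12.5,
                             fixation = 7.5) {
  if (blocksPerRun %% N_SCALES != 0L)
    stop("blocksPerRun must be divisible by 6 (equal blocks per scale per run)")
  cycle <- blockDuration + fixation
  if (is.null(volumesPerRun))
    volumesPerRun <- ceiling((blocksPerRun * cycle + 20) / tr)
  perScale <- blocksPerRun %/% N_SCALES
  blocks <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nRuns), function(r) {
      scales <- rep(1:N_SCALES, each = perScale)
      # two locations per scale: ids 2s-1, 2s
      locs <- unlist(lapply(1:N_SCALES, function(s)
        rep(c(2L * s - 1L, 2L * s), length.out = perScale)))
      ord <- sample.int(blocksPerRun)
      data.frame(run = r,
                 onset = (seq_len(blocksPerRun) - 1) * cycle,
                 duration = blockDuration,
                 scale = scales[ord],
                 location = locs[ord],
                 task = "spatial",
                 stringsAsFactors = FALSE)
    }))
  })
  new("Paradigm", blocks = blocks, trSeconds = tr,
      volumesPerRun = as.integer(volumesPerRun), nRuns = as.integer(nRuns))
}

defaultGradientMask <- function(dim, axis = 2L) {
  mask <- array(FALSE, dim)
  lo <- pmax(1L, floor(dim / 4) + 1L)
  hi <- pmin(dim, ceiling(3 * dim / 4))
  rng <- lapply(1:3, function(a) if (a == axis) seq_len(dim[a]) else lo[a]:hi[a])
  mask[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  mask
}

#' Generate a ground-truth tuning field with a linear scale gradient
#'
#' Inside the gradient mask, true tuning centers follow
#' `intercept + slope * coordinate_mm` along the chosen axis plus Gaussian
#' jitter, clipped to the scale axis [1, 6]; outside the mask voxels are
#' untuned (amplitude 0).
#'
#' @param dim grid shape in voxels (default 20 x 40 x 20 at 3 mm, the
#'   functional resolution emulated).
#' @param voxelSizeMm isotropic voxel size.
#' @param mask logical array marking the gradient region; default is a
#'   central slab spanning the full axis extent.
#' @param axis axis along which the center varies (2 = posterior-anterior Y).
#' @param slope scale units per mm; default spans centers 1 to 6 across the
#'   mask's axis extent.
#' @param intercept center at coordinate 0 mm; default puts center 1 at the
#'   posterior edge of the mask.
#' @param jitterSd SD of the center jitter, scale units.
#' @param amplitude,width true tuning amplitude (percent signal change) and
#'   width (scale units) inside the mask.
#' @param seed RNG seed.
#' @return a [TuningField].
#' @export
generateTuningField <- function(dim = c(20L, 40L, 20L), voxelSizeMm = 3,
                                mask = NULL, axis = 2L, slope = NULL,
                                intercept = NULL, jitterSd = 0,
                                amplitude = 1, width = 1, seed = 1) {
  dim <- as.integer(dim)
  if (is.null(mask)) mask <- defaultGradientMask(dim, axis)
  if (!any(mask)) stop("gradient mask is empty")
  if (!is.null(slope) && !is.finite(slope)) stop("slope must be finite")
  idx <- which(mask, arr.ind = TRUE)
  coordMm <- (idx[, axis] - 1) * voxelSizeMm
  rng <- range(coordMm)
  if (is.null(slope))
    slope <- if (diff(rng) > 0) 5 / diff(rng) else 0
  if (is.null(intercept)) intercept <- 1 - slope * rng[1]
  cen <- array(3.5, dim)
  amp <- array(0, dim)
  wid <- array(width, dim)
  jit <- withSeed(seed, rnorm(nrow(idx), 0, jitterSd))
  cen[mask] <- pmin(6, pmax(1, intercept + slope * coordMm + jit))
  amp[mask] <- amplitude
  new("TuningField", dim = dim, voxelSizeMm = voxelSizeMm, amplitude = amp,
      center = cen, width = wid, mask = mask, axis = as.integer(axis),
      slope = slope, intercept = intercept)
}

#' Noise specification for simulated BOLD
#'
#' @param ar AR coefficients, order <= 2; must be stationary.
#' @param innovationSd innovation SD in scanner units.
#' @param driftAmplitude,driftPeriodSeconds single low-frequency cosine
#'   drift (amplitude in scanner units).
#' @param baseline baseline intensity (> 0).
#' @return a [NoiseSpec].
#' @export
noiseSpec <- function(ar = c(0.3, 0.2), innovationSd = 10,
                      driftAmplitude = 5, driftPeriodSeconds = 128,
                      baseline = 1000) {
  new("NoiseSpec", ar = ar, innovationSd = innovationSd,
      driftAmplitude = driftAmplitude,
      driftPeriodSeconds = driftPeriodSeconds, baseline = baseline)
}

gaussianTuningCurve <- function(amplitude, center, width, s = 1:N_SCALES) {
  amplitude * exp(-(outer(center, s, "-"))^2 / (2 * width^2))
}

#' Simulate 4D BOLD volumes from a paradigm and a tuning field
#'
#' Per-scale responses follow the same parametric Gaussian tuning form the
#' fitter assumes, `amplitude * exp(-(s - center)^2 / (2 width^2))`, in
#' percent-signal-change units. The activation enters as a zero-mean
#' modulation of the HRF-convolved scale predictors around the baseline, so
#' the voxel mean equals the baseline (up to drift and noise) and injected
#' amplitudes are exact in percent-signal-change units after scaling.
#' AR noise and a demeaned cosine drift are added on top.
#'
#' @param paradigm a [Paradigm].
#' @param field a [TuningField] (its grid defines the volume shape).
#' @param noise a [NoiseSpec].
#' @param seed RNG seed.
#' @param hrf HRF kernel (default [hrfKernel()] at 0.1 s).
#' @return list with `runs` (list of 4D arrays x,y,z,time), `trueResponse`
#'   (voxels x 6 matrix of injected per-scale responses, percent units) and
#'   `design` (the [DesignMatrix] used for injection).
#' @export
simulateBold <- function(paradigm, field, noise, seed = 1,
                         hrf = hrfKernel(0.1)) {
  stopifnot(is(paradigm, "Paradigm"), is(field, "TuningField"),
            is(noise, "NoiseSpec"))
  design <- buildDesignMatrix(paradigm, hrf = hrf)
  X <- design@matrix[, paste0("scale", 1:N_SCALES), drop = FALSE]
  runIndex <- design@runIndex
  nVol <- paradigm@volumesPerRun
  tr <- paradigm@trSeconds
  d <- field@dim
  V <- prod(d)
  Rmat <- gaussianTuningCurve(as.numeric(field@amplitude),
                              as.numeric(field@center),
                              as.numeric(field@width))
  Rmat[as.numeric(field@amplitude) == 0, ] <- 0
  tVol <- (seq_len(nVol) - 1) * tr
  drift <- noise@driftAmplitude * cos(2 * pi * tVol / noise@driftPeriodSeconds)
  drift <- drift - mean(drift)
  runs <- withSeed(seed, {
    lapply(seq_len(paradigm@nRuns), function(r) {
      Xr <- X[runIndex == r, , drop = FALSE]
      Xc <- sweep(Xr, 2L, colMeans(Xr), "-")
      sig <- noise@baseline * (1 + (Xc %*% t(Rmat)) / 100) + drift
      if (noise@innovationSd > 0) {
        e <- matrix(rnorm(nVol * V, 0, noise@innovationSd), nVol, V)
        if (length(noise@ar) > 0)
          e <- stats::filter(e, noise@ar, method = "recursive")
        sig <- sig + as.matrix(e)
      }
      array(t(sig), dim = c(d, nVol))
    })
  })
  list(runs = runs, trueResponse = Rmat, design = design)
}

#' Generate nested geographic stimulus sets
#'
#' Scatters items around a random center per location, with per-scale
#' dispersion growing with scale, so mean log pairwise distance increases
#' (log-linearly for log-spaced dispersions). Item placement uses
#' great-circle destination points (bearing + distance), exact at any
#' dispersion.
#'
#' @param locationsPerScale locations per scale (study default 2).
#' @param itemsPerLocation items per location (>= 2; study default 8).
#' @param dispersionKm per-scale dispersion, scales 3-6 (neighborhood, city,
#'   country, continent); must be positive and increasing.
#' @param seed RNG seed.
#' @param radiusKm sphere radius (mean Earth radius 6371 km).
#' @return a [GeoStimulusSet].
#' @export
generateGeoStimuli <- function(locationsPerScale = 2, itemsPerLocation = 8,
                               dispersionKm = c(0.5, 10, 500, 5000),
                               seed = 1, radiusKm = 6371) {
  if (itemsPerLocation < 2) stop("itemsPerLocation must be >= 2")
  if (length(dispersionKm) != 4L || any(dispersionKm <= 0) ||
      is.unsorted(dispersionKm, strictly = TRUE))
    stop("dispersionKm must be 4 positive increasing values (scales 3-6)")
  entries <- withSeed(seed, {
    do.call(rbind, lapply(3:6, function(s) {
      disp <- dispersionKm[s - 2L]
      do.call(rbind, lapply(seq_len(locationsPerScale), function(l) {
        cLon <- runif(1, -180, 180)
        cLat <- asin(runif(1, -0.9, 0.9)) * 180 / pi
        bearing <- runif(itemsPerLocation, 0, 360)
        dist <- abs(rnorm(itemsPerLocation, 0, disp))
        p <- geosphere::destPoint(c(cLon, cLat), bearing, dist,
                                  r = radiusKm)
        data.frame(scale = s, location = sprintf("s%d_loc%d", s, l),
                   item = sprintf("s%d_loc%d_item%d", s, l,
                                  seq_len(itemsPerLocation)),
                   lat = p[, "lat"], lon = p[, "lon"],
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  new("GeoStimulusSet", entries = entries)
}

#' Generate behavioral ratings with target scale correlations
#'
#' Draws ratings so each measure's expected Pearson correlation with the
#' scale index (1-6) matches its target: the standardized rating is
#' `target * z(scale) + sqrt(1 - target^2) * noise`, rescaled to the 1-7
#' range and clipped. A target of +/-1 therefore yields perfectly
#' (anti-)ordered ratings with no noise.
#'
#' Defaults are the study's reported correlations: familiarity -0.72,
#' difficulty 0.39, first-person perspective -0.81, third-person +0.80;
#' emotion 0 (no reported scale effect); map-strategy use +0.80.
#'
#' @param targets named numeric vector of target correlations in [-1, 1] for
#'   measures familiarity, emotion, difficulty (location-level) and
#'   firstPerson, thirdPerson, mapStrategy (scale-level).
#' @param nSubjects number of subjects (study default 19).
#' @param seed RNG seed.
#' @return a [RatingsTable].
#' @export
generateRatings <- function(targets = c(familiarity = -0.72, emotion = 0,
                                        difficulty = 0.39,
                                        firstPerson = -0.81,
                                        thirdPerson = 0.80,
                                        mapStrategy = 0.80),
                            nSubjects = 19, seed = 1) {
  need <- c("familiarity", "emotion", "difficulty", "firstPerson",
            "thirdPerson", "mapStrategy")
  if (!all(need %in% names(targets)))
    stop("targets must name: ", paste(need, collapse = ", "))
  if (any(abs(targets) > 1)) stop("target correlations must lie in [-1, 1]")
  # noiseFactor sqrt(L) keeps the target exact for the analyzed quantity:
  # location-level measures are averaged over the L locations per scale
  # before correlating with scale, which shrinks their noise by sqrt(L)
  drawMeasure <- function(target, scaleIdx, noiseFactor = 1) {
    z <- (scaleIdx - mean(1:6)) / stats::sd(1:6)
    std <- target * z + noiseFactor * sqrt(1 - target^2) * rnorm(length(scaleIdx))
    pmin(7, pmax(1, 4 + std))
  }
  withSeed(seed, {
    locScale <- rep(1:6, each = 2)  # 12 locations, 2 per scale
    loc <- do.call(rbind, lapply(seq_len(nSubjects), function(su) {
      nf <- sqrt(2)  # 2 locations per scale
      data.frame(subject = su, location = 1:12, scale = locScale,
                 familiarity = drawMeasure(targets["familiarity"], locScale, nf),
                 emotion = drawMeasure(targets["emotion"], locScale, nf),
                 difficulty = drawMeasure(targets["difficulty"], locScale, nf))
    }))
    scl <- do.call(rbind, lapply(seq_len(nSubjects), function(su) {
      data.frame(subject = su, scale = 1:6,
                 firstPerson = drawMeasure(targets["firstPerson"], 1:6),
                 thirdPerson = drawMeasure(targets["thirdPerson"], 1:6),
                 mapStrategy = drawMeasure(targets["mapStrategy"], 1:6))
    }))
    new("RatingsTable", locationRatings = loc, scaleRatings = scl,
        bounds = c(1, 7))
  })
}
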