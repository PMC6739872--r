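# Boxcar construction and HRF convolution happen on a fine time grid
# (default 0.1 s) and are then subsampled at volume acquisition times
# t = (i - 1) * TR; convolution is a plain Riemann sum so an independent
# direct-convolution oracle can reproduce every column exactly.

fineBoxcar <- function(onsets, durations, tFine) {
  x <- numeric(length(tFine))
  for (i in seq_along(onsets)) {
    x[tFine >= onsets[i] - 1e-9 & tFine < onsets[i] + durations[i] - 1e-9] <- 1
  }
  x
}

convolveFine <- function(x, hrf) {
  dt <- attr(hrf, "dt")
  y <- stats::convolve(x, rev(as.numeric(hrf)), type = "open") * dt
  y[seq_along(x)]
}

sampleAtVolumes <- function(yFine, tFine, nVolumes, tr) {
  tVol <- (seq_len(nVolumes) - 1) * tr
  idx <- round(tVol / (tFine[2] - tFine[1])) + 1L
  if (any(idx > length(yFine))) stop("volume times extend past the fine grid")
  yFine[idx]
}

#' Build a GLM design matrix from a block paradigm
#'
#' One HRF-convolved boxcar column per spatial scale (each spanning the full
#' block, target plus the four comparisons), an optional lexical-control
#' column, optional unconvolved nuisance columns, optional low-frequency
#' cosine/sine drift regressors, and one intercept column per run.
#'
#' Boxcars are built per run on a fine time grid (`fineDt`), convolved with
#' the kernel, and subsampled at volume onsets.
#'
#' @param paradigm a [Paradigm].
#' @param nuisance optional matrix/data.frame of nuisance regressors, one row
#'   per acquired volume across all runs; appended unconvolved.
#' @param hrf kernel from [hrfKernel()]; its `dt` must equal `fineDt`.
#' @param highpassCycles number of low-frequency Fourier cycles per run to
#'   model as cosine/sine nuisance pairs (0 = none).
#' @param fineDt fine-grid resolution in seconds; the TR must be a multiple.
#' @return a [DesignMatrix].
#' @export
buildDesignMatrix <- function(paradigm, nuisance = NULL,
                              hrf = hrfKernel(fineDt), highpassCycles = 0,
                              fineDt = 0.1) {
  stopifnot(is(paradigm, "Paradigm"))
  if (abs(attr(hrf, "dt") - fineDt) > 1e-12)
    stop("hrf kernel dt must equal fineDt")
  tr <- paradigm@trSeconds
  if (abs(tr / fineDt - round(tr / fineDt)) > 1e-9)
    stop("TR must be an integer multiple of fineDt")
  nVol <- paradigm@volumesPerRun
  runLen <- nVol * tr
  b <- paradigm@blocks
  bad <- which(b$onset + b$duration > runLen + 1e-9)
  if (length(bad))
    stop(sprintf("block at onset %.1f s (run %d) extends past the acquisition window",
                 b$onset[bad[1]], b$run[bad[1]]))
  runs <- seq_len(paradigm@nRuns)
  tFine <- seq(0, runLen + 1e-9, by = fineDt)
  hasLexical <- any(b$task == "lexical")

  perRun <- lapply(runs, function(r) {
    br <- b[b$run == r, ]
    cols <- sapply(1:N_SCALES, function(s) {
      bs <- br[br$task == "spatial" & br$scale == s, ]
      if (nrow(bs) == 0L) return(numeric(nVol))
      sampleAtVolumes(convolveFine(fineBoxcar(bs$onset, bs$duration, tFine), hrf),
                      tFine, nVol, tr)
    })
    colnames(cols) <- paste0("scale", 1:N_SCALES)
    if (hasLexical) {
      bl <- br[br$task == "lexical", ]
      lex <- if (nrow(bl)) {
        sampleAtVolumes(convolveFine(fineBoxcar(bl$onset, bl$duration, tFine), hrf),
                        tFine, nVol, tr)
      } else numeric(nVol)
      cols <- cbind(cols, lexical = lex)
    }
    cols
  })
  X <- do.call(rbind, perRun)
  runIndex <- rep(runs, each = nVol)
  taskCols <- colnames(X)

  if (highpassCycles > 0) {
    tVol <- (seq_len(nVol) - 1) * tr
    for (r in runs) {
      for (cyc in seq_len(highpassCycles)) {
        cc <- ss <- numeric(nrow(X))
        cc[runIndex == r] <- cos(2 * pi * cyc * tVol / runLen)
        ss[runIndex == r] <- sin(2 * pi * cyc * tVol / runLen)
        X <- cbind(X, cc, ss)
        colnames(X)[ncol(X) - 1:0] <- sprintf(c("hp_cos%d_run%d", "hp_sin%d_run%d"),
                                              cyc, r)
      }
    }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(X))
      stop(sprintf("nuisance has %d rows but the acquisition has %d volumes",
                   nrow(nuisance), nrow(X)))
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  for (r in runs) {
    ic <- as.numeric(runIndex == r)
    X <- cbind(X, ic)
    colnames(X)[ncol(X)] <- paste0("intercept_run", r)
  }
  new("DesignMatrix", matrix = X, runIndex = as.integer(runIndex),
      trSeconds = tr, taskColumns = taskCols)
}

#' Parametric-modulation regressor from behavioral ratings
#'
#' Z-transforms one rating measure within subject, assigns each spatial block
#' the z-score of its location (location-level measures) or scale
#' (scale-level measures), scales the block's boxcar by it, convolves with
#' the HRF and mean-centers the result. Per-block covariates (e.g. response
#' times) can be supplied directly through `values`.
#'
#' @param paradigm a [Paradigm].
#' @param ratings a [RatingsTable] (ignored when `values` is given).
#' @param measure one of "familiarity", "emotion", "difficulty" (by
#'   location) or "firstPerson", "thirdPerson", "mapStrategy" (by scale).
#' @param hrf kernel from [hrfKernel()].
#' @param subject subject id to pull ratings for.
#' @param values optional per-block numeric covariate (length = number of
#'   spatial blocks, paradigm order); z-transformed before use.
#' @param fineDt fine time grid in seconds.
#' @return numeric regressor (one value per volume), mean-centered, with a
#'   `label` attribute.
#' @export
buildModulationRegressor <- function(paradigm, ratings = NULL, measure,
                                     hrf = hrfKernel(fineDt), subject = 1,
                                     values = NULL, fineDt = 0.1) {
  stopifnot(is(paradigm, "Paradigm"))
  b <- paradigm@blocks
  sp <- b[b$task == "spatial", ]
  if (is.null(values)) {
    stopifnot(is(ratings, "RatingsTable"))
    locMeasures <- c("familiarity", "emotion", "difficulty")
    sclMeasures <- c("firstPerson", "thirdPerson", "mapStrategy")
    if (measure %in% locMeasures) {
      tab <- ratings@locationRatings
      tab <- tab[tab$subject == subject, ]
      z <- zTransformWithinSubject(tab[[measure]])
      key <- tab$location
      blockKey <- sp$location
    } else if (measure %in% sclMeasures) {
      tab <- ratings@scaleRatings
      tab <- tab[tab$subject == subject, ]
      z <- zTransformWithinSubject(tab[[measure]])
      key <- tab$scale
      blockKey <- sp$scale
    } else {
      stop(sprintf("unknown measure '%s'", measure))
    }
    idx <- match(blockKey, key)
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop(sprintf("no '%s' rating for block at onset %.1f s (run %d)",
                   measure, sp$onset[miss], sp$run[miss]))
    }
    values <- as.numeric(z)[idx]
  } else {
    if (length(values) != nrow(sp))
      stop("values must have one entry per spatial block")
    values <- as.numeric(zTransformWithinSubject(values))
  }
  tr <- paradigm@trSeconds
  nVol <- paradigm@volumesPerRun
  runLen <- nVol * tr
  tFine <- seq(0, runLen + 1e-9, by = fineDt)
  out <- unlist(lapply(seq_len(paradigm@nRuns), function(r) {
    sel <- sp$run == r
    x <- numeric(length(tFine))
    if (any(sel)) {
      on <- sp$onset[sel]; du <- sp$duration[sel]; v <- values[sel]
      for (i in seq_along(on))
        x[tFine >= on[i] - 1e-9 & tFine < on[i] + du[i] - 1e-9] <- v[i]
    }
    sampleAtVolumes(convolveFine(x, hrf), tFine, nVol, tr)
  }))
  out <- out - mean(out)
  attr(out, "label") <- paste0("mod_", measure)
  out
}
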