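#' Region-of-interest condition betas
#'
#' Per subject, the mean beta over mask voxels for each of the six scales;
#' then across-subject mean and standard error (random-effects ROI summary).
#'
#' @param subjectMaps list of [ScaleBetaMap] on a common grid.
#' @param mask logical 3D array; must intersect the grid.
#' @param regionLabel label for the summary.
#' @return list: `region`, `mean` (6), `se` (6), `n`, `subjectMeans`
#'   (subjects x 6 matrix).
#' @export
roiBetas <- function(subjectMaps, mask, regionLabel = "roi") {
  stopifnot(length(subjectMaps) >= 1L)
  d <- dim(subjectMaps[[1]]@betas)[1:3]
  if (!identical(dim(mask), as.integer(d)) && !identical(dim(mask), d))
    stop("mask grid does not match the beta maps")
  vox <- which(mask)
  if (!length(vox)) stop("mask does not intersect the grid")
  sm <- t(vapply(subjectMaps, function(m) {
    B <- matrix(m@betas, prod(d), N_SCALES)
    colMeans(B[vox, , drop = FALSE])
  }, numeric(N_SCALES)))
  n <- nrow(sm)
  mu <- colMeans(sm)
  se <- if (n > 1) apply(sm, 2L, stats::sd) / sqrt(n) else rep(0, N_SCALES)
  list(region = regionLabel, mean = mu, se = se, n = n, subjectMeans = sm)
}

#' Event-related average around block onsets
#'
#' Average percent-signal-change time course over `nVolumes` volumes
#' following each block's onset, per scale, across blocks and runs. Onsets
#' are aligned to the nearest acquisition at or after the onset (no temporal
#' upsampling). Blocks whose window extends past the run are dropped with a
#' warning.
#'
#' @param runs list of 4D arrays (x, y, z, time), already percent-signal-
#'   change scaled, one per run of the paradigm.
#' @param paradigm the [Paradigm] that generated them.
#' @param mask logical 3D array averaged over.
#' @param nVolumes window length in volumes (study value 10; 25 s at TR
#'   2.5 s).
#' @return 6 x nVolumes matrix of mean courses (rows = scales), with
#'   attribute `nBlocks` (blocks contributing per scale).
#' @export
eventRelatedAverage <- function(runs, paradigm, mask, nVolumes = 10) {
  stopifnot(is(paradigm, "Paradigm"), length(runs) == paradigm@nRuns)
  tr <- paradigm@trSeconds
  vox <- which(mask)
  if (!length(vox)) stop("mask does not intersect the grid")
  acc <- matrix(0, N_SCALES, nVolumes)
  cnt <- integer(N_SCALES)
  dropped <- 0L
  b <- paradigm@blocks
  for (r in seq_along(runs)) {
    d <- dim(runs[[r]])
    series <- matrix(runs[[r]], prod(d[1:3]), d[4])[vox, , drop = FALSE]
    m <- colMeans(series)
    br <- b[b$run == r & b$task == "spatial", ]
    for (i in seq_len(nrow(br))) {
      v0 <- ceiling(br$onset[i] / tr - 1e-9) + 1L
      if (v0 + nVolumes - 1L > d[4]) {
        dropped <- dropped + 1L
        next
      }
      s <- br$scale[i]
      acc[s, ] <- acc[s, ] + m[v0:(v0 + nVolumes - 1L)]
      cnt[s] <- cnt[s] + 1L
    }
  }
  if (dropped > 0L)
    warning(sprintf("%d truncated block(s) dropped from the event-related average",
                    dropped))
  out <- acc / ifelse(cnt > 0L, cnt, NA_integer_)
  rownames(out) <- SCALE_LABELS
  attr(out, "nBlocks") <- cnt
  out
}

#' Percent overlap of a region with a label parcellation
#'
#' For each parcellation label, 100 * |region intersect label| / |region|;
#' voxels with label 0 are reported as unassigned. Percentages sum to 100.
#'
#' @param region logical 3D array.
#' @param parcellation integer 3D array of network labels on the same grid
#'   (0 = unassigned).
#' @param regionLabel label for the report.
#' @return list: `region`, `overlap` (data.frame label/nVoxels/percent),
#'   `unassignedPercent`.
#' @export
networkOverlap <- function(region, parcellation, regionLabel = "region") {
  if (!identical(dim(region), dim(parcellation)))
    stop("region and parcellation grids do not match")
  vox <- which(region)
  if (!length(vox)) stop("region mask is empty")
  labs <- parcellation[vox]
  total <- length(vox)
  pos <- sort(unique(labs[labs > 0]))
  counts <- vapply(pos, function(l) sum(labs == l), 0L)
  list(region = regionLabel,
       overlap = data.frame(label = pos, nVoxels = counts,
                            percent = 100 * counts / total),
       unassignedPercent = 100 * sum(labs == 0) / total)
}
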