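#' Repeated-measures ANOVA across the six scale conditions
#'
#' Single-factor within-subject ANOVA on a subjects x 6 beta matrix:
#' F = MS_condition / MS_condition-by-subject with df (5, 5(n-1)). A table
#' with no variance anywhere returns F = 0, p = 1.
#'
#' @param betas subjects x 6 numeric matrix, no missing cells.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @seealso [rmAnovaScaleMap()] for the vectorized many-voxel version.
#' @export
rmAnovaScale <- function(betas) {
  betas <- as.matrix(betas)
  if (anyNA(betas)) stop("missing cells are not allowed (no imputation)")
  if (nrow(betas) < 2L || ncol(betas) != N_SCALES)
    stop("need >= 2 subjects and exactly 6 conditions")
  res <- rmAnovaScaleMap(array(betas, c(dim(betas), 1L)))
  list(F = res$F[1], p = res$p[1], df1 = res$df1, df2 = res$df2)
}

#' Vectorized repeated-measures ANOVA over many voxels
#'
#' @param betaArray subjects x 6 x voxels array.
#' @return list of vectors `F`, `p` (length voxels) and scalars `df1`, `df2`.
#' @export
rmAnovaScaleMap <- function(betaArray) {
  d <- dim(betaArray)
  n <- d[1]; k <- d[2]; V <- d[3]
  if (anyNA(betaArray)) stop("missing cells are not allowed (no imputation)")
  M <- matrix(betaArray, n * k, V)
  grand <- colMeans(M)
  # condition means: k x V ; subject means: n x V
  condMean <- matrix(0, k, V)
  for (j in seq_len(k))
    condMean[j, ] <- colMeans(M[(j - 1L) * n + seq_len(n), , drop = FALSE])
  subjMean <- matrix(0, n, V)
  for (i in seq_len(n))
    subjMean[i, ] <- colMeans(M[seq(i, n * k, by = n), , drop = FALSE])
  ssCond <- n * colSums((condMean - rep(grand, each = k))^2)
  resid <- M -
    subjMean[rep(seq_len(n), k), ] -
    condMean[rep(seq_len(k), each = n), ] +
    rep(grand, each = n * k)
  ssErr <- colSums(matrix(resid, n * k, V)^2)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  Fv <- ifelse(ssErr > 1e-24, (ssCond / df1) / (ssErr / df2),
               ifelse(ssCond > 1e-24, Inf, 0))
  pv <- ifelse(Fv == 0 & ssErr <= 1e-24, 1,
               stats::pf(Fv, df1, df2, lower.tail = FALSE))
  list(F = Fv, p = pv, df1 = df1, df2 = df2)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up FDR adjustment (delegating to [stats::p.adjust()]) plus a
#' selection mask at level `q`.
#'
#' @param pvals p-values in [0, 1] (NA allowed, never selected).
#' @param q FDR level.
#' @return list with `qvals` (monotone adjusted values) and `selected`.
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(list(qvals = numeric(0), selected = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  qvals <- stats::p.adjust(pvals, method = "BH")
  sel <- !is.na(qvals) & qvals <= q
  list(qvals = qvals, selected = sel)
}

#' Scale with maximal activity
#'
#' Ordinal preferred scale: index of the maximum of the 6 condition betas.
#' Ties are broken by the smallest index.
#'
#' @param betas 6-vector of finite condition betas.
#' @return integer in 1..6.
#' @export
maxScale <- function(betas) {
  if (length(betas) != N_SCALES || any(!is.finite(betas)))
    stop("betas must be 6 finite values")
  which.max(betas)
}

#' Bounded Gaussian tuning fit to six condition betas
#'
#' Fits `amplitude * exp(-(s - center)^2 / (2 width^2))` at s = 1..6 to the
#' min-subtracted beta vector by bounded least squares (L-BFGS-B) with
#' multi-start: the center is started at each of s = 1..6 to avoid local
#' minima for boundary-tuned voxels. Bounds: amplitude [0, 100], center
#' [-100, 100], width (0, 100]. r-squared is 1 - SS_res/SS_tot on the
#' min-subtracted vector; a flat vector has undefined r-squared and fails
#' the gate.
#'
#' @param betas 6 finite condition betas.
#' @param gate r-squared gate (default 0.7).
#' @param boundsAmplitude,boundsCenter,boundsWidth fit bounds.
#' @return list: `amplitude`, `center`, `width`, `r2`, `peakScale` (center
#'   clipped to [1, 6]), `maxScale`, `passesGate`, `converged`.
#' @export
fitGaussianTuning <- function(betas, gate = 0.7,
                              boundsAmplitude = c(0, 100),
                              boundsCenter = c(-100, 100),
                              boundsWidth = c(1e-3, 100)) {
  if (length(betas) != N_SCALES || any(!is.finite(betas)))
    stop("betas must be 6 finite values")
  ms <- maxScale(betas)
  y <- betas - min(betas)
  ssTot <- sum((y - mean(y))^2)
  failed <- list(amplitude = NA_real_, center = NA_real_, width = NA_real_,
                 r2 = NA_real_, peakScale = NA_real_, maxScale = ms,
                 passesGate = FALSE, converged = FALSE)
  if (ssTot < 1e-24) return(failed)
  s <- 1:N_SCALES
  sse <- function(par) {
    pred <- par[1] * exp(-(s - par[2])^2 / (2 * par[3]^2))
    sum((y - pred)^2)
  }
  best <- NULL
  a0 <- min(max(max(y), boundsAmplitude[1] + 1e-6), boundsAmplitude[2])
  for (c0 in s) {
    fit <- tryCatch(
      stats::optim(c(a0, c0, 1), sse, method = "L-BFGS-B",
                   lower = c(boundsAmplitude[1], boundsCenter[1], boundsWidth[1]),
                   upper = c(boundsAmplitude[2], boundsCenter[2], boundsWidth[2])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(failed)
  r2 <- 1 - best$value / ssTot
  list(amplitude = best$par[1], center = best$par[2], width = best$par[3],
       r2 = r2, peakScale = min(6, max(1, best$par[2])), maxScale = ms,
       passesGate = is.finite(r2) && r2 > gate, converged = TRUE)
}

#' Fit Gaussian tuning at every voxel of a beta map
#'
#' @param map a [ScaleBetaMap] or [GroupBetaMap] (its mean is used).
#' @param mask optional logical array restricting the fit (e.g. the
#'   ANOVA-selected voxels); default all voxels.
#' @param gate r-squared gate (default 0.7).
#' @return a [VoxelTuning].
#' @export
fitTuningMap <- function(map, mask = NULL, gate = 0.7) {
  arr <- if (is(map, "GroupBetaMap")) map@mean else betaArray(map)
  d <- dim(arr)[1:3]
  B <- matrix(arr, prod(d), N_SCALES)
  vox <- if (is.null(mask)) seq_len(prod(d)) else which(mask)
  if (!length(vox)) stop("mask selects no voxels")
  rows <- lapply(vox, function(v) {
    f <- fitGaussianTuning(B[v, ], gate = gate)
    data.frame(voxel = v, amplitude = f$amplitude, center = f$center,
               width = f$width, r2 = f$r2, peakScale = f$peakScale,
               maxScale = f$maxScale, passesGate = f$passesGate)
  })
  fits <- do.call(rbind, rows)
  ai <- arrayInd(fits$voxel, d)
  fits$x <- ai[, 1]; fits$y <- ai[, 2]; fits$z <- ai[, 3]
  new("VoxelTuning", fits = fits, dim = as.integer(d), gate = gate)
}

#' Voxelwise scale-sensitivity selection
#'
#' Repeated-measures ANOVA across the six condition betas at every voxel of
#' the analysis mask, BH-FDR correction across those voxels, selection at
#' q < alpha.
#'
#' @param subjectMaps list of [ScaleBetaMap] (>= 2 subjects, same grid).
#' @param mask logical analysis mask (default: all voxels).
#' @param alpha FDR level (study value 0.01).
#' @return a [SelectivityMask] (cluster ids all 0 until
#'   [applyClusterThreshold()] is applied).
#' @export
selectScaleSensitive <- function(subjectMaps, mask = NULL, alpha = 0.01) {
  stopifnot(length(subjectMaps) >= 2L)
  d <- dim(subjectMaps[[1]]@betas)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- which(mask)
  n <- length(subjectMaps)
  arr <- array(NA_real_, c(n, N_SCALES, length(vox)))
  for (i in seq_len(n)) {
    B <- matrix(subjectMaps[[i]]@betas, prod(d), N_SCALES)
    arr[i, , ] <- t(B[vox, , drop = FALSE])
  }
  res <- rmAnovaScaleMap(arr)
  fdr <- fdrBH(res$p, q = alpha)
  mk <- function(vals, fill = NA_real_) {
    a <- array(fill, d); a[vox] <- vals; a
  }
  sel <- array(FALSE, d); sel[vox] <- fdr$selected
  new("SelectivityMask", F = mk(res$F), p = mk(res$p), q = mk(fdr$qvals),
      selected = sel, cluster = array(0L, d), alpha = alpha)
}

connectivityOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, , drop = FALSE]
  # one direction per neighbor pair
  g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
}

labelComponents <- function(selected, connectivity = 6) {
  d <- dim(selected)
  vox <- which(selected)
  lab <- array(0L, d)
  if (!length(vox)) return(lab)
  L <- array(seq_len(prod(d)), d)
  offs <- connectivityOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    x1 <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    y1 <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    z1 <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    I1 <- L[x1, y1, z1]
    I2 <- L[x1 + o[1], y1 + o[2], z1 + o[3]]
    both <- selected[I1] & selected[I2]
    from <- c(from, I1[both]); to <- c(to, I2[both])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, vox), match(to, vox)))
  comp <- igraph::components(g)
  lab[vox] <- comp$membership
  lab
}

#' Remove small clusters from a selectivity mask
#'
#' Labels the connected components of the selected voxels (6-, 18- or
#' 26-neighborhood) and removes components smaller than `minVoxels`.
#' Surviving clusters get consecutive ids ordered by decreasing size.
#'
#' @param mask a [SelectivityMask].
#' @param minVoxels minimum cluster extent in voxels (>= 1).
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full).
#' @return the updated [SelectivityMask].
#' @export
applyClusterThreshold <- function(mask, minVoxels = 5, connectivity = 6) {
  stopifnot(is(mask, "SelectivityMask"))
  if (minVoxels < 1) stop("minVoxels must be >= 1")
  lab <- labelComponents(mask@selected, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minVoxels)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  newId <- integer(length(sizes))
  newId[ord] <- seq_along(ord)
  relab <- array(0L, dim(lab))
  pos <- lab > 0
  relab[pos] <- newId[lab[pos]]
  sel <- relab > 0
  initialize(mask, selected = sel, cluster = relab)
}
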