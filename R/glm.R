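#' Percent-signal-change scaling
#'
#' Scales each voxel time series to 100 * (x - mean) / mean. Voxels whose
#' mean intensity is at or below `minIntensity` (default 0; raw scanner data
#' typically uses 100) are excluded: their output is set to NA and flagged,
#' no error is raised.
#'
#' @param series numeric vector, volumes x voxels matrix, or 4D array
#'   (x, y, z, time).
#' @param minIntensity exclusion threshold on the voxel mean.
#' @return object of the same shape with attribute `excluded` (logical per
#'   voxel).
#' @export
percentSignalChange <- function(series, minIntensity = 0) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    m <- matrix(series, prod(d[1:3]), d[4])
    out <- percentSignalChange(t(m), minIntensity)
    res <- array(t(out), dim = d)
    attr(res, "excluded") <- array(attr(out, "excluded"), dim = d[1:3])
    return(res)
  }
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, ncol = 1L) else as.matrix(series)
  mu <- colMeans(m)
  excluded <- !is.finite(mu) | mu <= minIntensity
  out <- 100 * sweep(m, 2L, mu, "-")
  out <- sweep(out, 2L, mu, "/")
  out[, excluded] <- NA_real_
  if (vec) out <- drop(out)
  attr(out, "excluded") <- excluded
  out
}

estimateAR2 <- function(E, runIndex) {
  # Yule-Walker AR(2) per column from within-run lagged autocovariances
  n <- nrow(E)
  ok1 <- c(FALSE, runIndex[-1] == runIndex[-n])
  ok2 <- c(FALSE, FALSE, runIndex[-(1:2)] == runIndex[-((n - 1):n)])
  c0 <- colSums(E^2)
  c1 <- colSums(E[ok1, , drop = FALSE] * E[which(ok1) - 1L, , drop = FALSE])
  c2 <- colSums(E[ok2, , drop = FALSE] * E[which(ok2) - 2L, , drop = FALSE])
  r1 <- ifelse(c0 > 1e-12, c1 / c0, 0)
  r2 <- ifelse(c0 > 1e-12, c2 / c0, 0)
  den <- 1 - r1^2
  a1 <- ifelse(abs(den) > 1e-12, r1 * (1 - r2) / den, 0)
  a2 <- ifelse(abs(den) > 1e-12, (r2 - r1^2) / den, 0)
  A <- cbind(a1, a2)
  # shrink the rare non-stationary estimate back inside the triangle
  bad <- !apply(A, 1L, arIsStationary)
  while (any(bad)) {
    A[bad, ] <- A[bad, , drop = FALSE] * 0.95
    bad <- !apply(A, 1L, arIsStationary)
  }
  A
}

whitenRows <- function(M, a, runIndex) {
  n <- nrow(M)
  keep <- c(FALSE, FALSE, runIndex[-(1:2)] == runIndex[-((n - 1):n)])
  idx <- which(keep)
  M[idx, , drop = FALSE] - a[1] * M[idx - 1L, , drop = FALSE] -
    a[2] * M[idx - 2L, , drop = FALSE]
}

#' Fit a voxelwise GLM with AR(2) prewhitening
#'
#' Two-pass estimator: ordinary least squares, Yule-Walker AR(2) fit to the
#' residuals (within runs), prewhitening of both data and design with the
#' estimated coefficients, and re-estimation on the whitened system. With
#' percent-signal-change input the betas are in percent-signal-change units.
#'
#' @param series volumes x voxels matrix (or vector) of (scaled) time
#'   series; NA columns (excluded voxels) yield NA fits.
#' @param design a [DesignMatrix]; must be full column rank.
#' @param arMethod "voxel" estimates AR(2) per voxel; "pooled" uses the
#'   median coefficients across voxels (one shared whitening).
#' @param whiten set FALSE for a plain OLS fit (AR coefficients still
#'   reported).
#' @return a [GlmFit].
#' @export
fitGlmAR2 <- function(series, design, arMethod = c("voxel", "pooled"),
                      whiten = TRUE) {
  arMethod <- match.arg(arMethod)
  stopifnot(is(design, "DesignMatrix"))
  X <- design@matrix
  Y <- if (is.null(dim(series))) matrix(series, ncol = 1L) else as.matrix(series)
  if (nrow(Y) != nrow(X))
    stop(sprintf("series has %d volumes but the design has %d rows",
                 nrow(Y), nrow(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  V <- ncol(Y)
  P <- ncol(X)
  good <- !apply(Y, 2L, anyNA)
  B <- matrix(NA_real_, V, P, dimnames = list(NULL, colnames(X)))
  SE <- matrix(NA_real_, V, P, dimnames = list(NULL, colnames(X)))
  A <- matrix(0, V, 2L)
  if (!any(good)) {
    return(new("GlmFit", betas = B, se = SE, arCoefficients = A,
               df = nrow(X) - P, columns = colnames(X)))
  }
  Yg <- Y[, good, drop = FALSE]
  B0 <- qr.coef(qx, Yg)
  E <- Yg - X %*% B0
  Ag <- estimateAR2(E, design@runIndex)
  dfOut <- nrow(X) - qx$rank
  if (!whiten) {
    # OLS path: AR coefficients are estimated and reported but not applied
    sigma2 <- colSums(E^2) / dfOut
    XtXinv <- chol2inv(qr.R(qx))
    SEg <- sqrt(outer(sigma2, diag(XtXinv)))
    B[good, ] <- t(B0)
    SE[good, ] <- SEg
    A[good, ] <- Ag
    return(new("GlmFit", betas = B, se = SE, arCoefficients = A,
               df = dfOut, columns = colnames(X)))
  }
  if (arMethod == "pooled") {
    a <- apply(Ag, 2L, stats::median)
    Xs <- whitenRows(X, a, design@runIndex)
    Ys <- whitenRows(Yg, a, design@runIndex)
    qs <- qr(Xs)
    Bs <- qr.coef(qs, Ys)
    Es <- Ys - Xs %*% Bs
    dfOut <- nrow(Xs) - qs$rank
    sigma2 <- colSums(Es^2) / dfOut
    XtXinv <- chol2inv(qr.R(qs))
    B[good, ] <- t(Bs)
    SE[good, ] <- sqrt(outer(sigma2, diag(XtXinv)))
    A[good, ] <- matrix(a, sum(good), 2L, byrow = TRUE)
  } else {
    gi <- which(good)
    dfOut <- NA_real_
    for (k in seq_along(gi)) {
      a <- Ag[k, ]
      Xs <- whitenRows(X, a, design@runIndex)
      ys <- whitenRows(Yg[, k, drop = FALSE], a, design@runIndex)
      fit <- stats::lm.fit(Xs, ys)
      dfk <- nrow(Xs) - fit$rank
      sigma2 <- sum(fit$residuals^2) / dfk
      R <- qr.R(fit$qr)
      # undo pivoting for chol2inv
      piv <- fit$qr$pivot
      XtXinv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
      B[gi[k], ] <- fit$coefficients[colnames(X)]
      SE[gi[k], ] <- sqrt(sigma2 * diag(XtXinv))
      A[gi[k], ] <- a
      dfOut <- dfk
    }
  }
  new("GlmFit", betas = B, se = SE, arCoefficients = A,
      df = dfOut, columns = colnames(X))
}

#' Group random-effects summary across subjects
#'
#' Across-subject mean, standard error and one-sample t statistic of the
#' condition betas at every voxel. Voxels where the across-subject SE is 0
#' report t as NA (missing, never infinite).
#'
#' @param subjectMaps list (>= 2) of [ScaleBetaMap] on identical grids.
#' @return a [GroupBetaMap].
#' @export
groupRandomEffects <- function(subjectMaps) {
  if (length(subjectMaps) < 2L) stop("need >= 2 subjects")
  stopifnot(all(vapply(subjectMaps, is, TRUE, "ScaleBetaMap")))
  d <- dim(subjectMaps[[1]]@betas)
  for (m in subjectMaps)
    if (!identical(dim(m@betas), d)) stop("subject grids differ")
  n <- length(subjectMaps)
  M <- vapply(subjectMaps, function(m) as.numeric(m@betas),
              numeric(prod(d)))
  mu <- rowMeans(M)
  ss <- rowSums((M - mu)^2)
  se <- sqrt(ss / (n - 1)) / sqrt(n)
  tt <- ifelse(se > 0, mu / se, NA_real_)
  new("GroupBetaMap", mean = array(mu, d), se = array(se, d),
      t = array(tt, d), n = as.integer(n))
}

#' Across-subject contrast on condition betas
#'
#' Weighted combination of each subject's condition betas followed by a
#' one-sample t-test across subjects (a paired contrast). Degenerate
#' across-subject SD of 0 yields t = NA.
#'
#' @param subjectBetas subjects x conditions numeric matrix.
#' @param weights contrast weights, length = number of conditions, not all
#'   zero.
#' @param sided "two" (default) or "one" (positive direction).
#' @return list with `estimate`, `t`, `df`, `p`.
#' @export
contrastBetas <- function(subjectBetas, weights, sided = c("two", "one")) {
  sided <- match.arg(sided)
  subjectBetas <- as.matrix(subjectBetas)
  if (length(weights) != ncol(subjectBetas))
    stop("weights length must match the number of conditions")
  if (all(weights == 0)) stop("contrast weights must not be all zero")
  combo <- drop(subjectBetas %*% weights)
  n <- length(combo)
  m <- mean(combo)
  se <- stats::sd(combo) / sqrt(n)
  if (!is.finite(se) || se == 0)
    return(list(estimate = m, t = NA_real_, df = n - 1L, p = NA_real_))
  tt <- m / se
  p <- if (sided == "two") 2 * stats::pt(-abs(tt), n - 1) else stats::pt(tt, n - 1, lower.tail = FALSE)
  list(estimate = m, t = tt, df = n - 1L, p = p)
}
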