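# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force discrete convolution on the fine grid: y[i] = sum_j x[j] h[i-j+1] dt
oracleConvolve <- function(x, h, dt) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(h))
    y[i] <- sum(x[i - seq_len(jmax) + 1] * h[seq_len(jmax)]) * dt
  }
  y
}

# spherical law of cosines great-circle distance
lawOfCosinesKm <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  cosd <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(1, pmax(-1, cosd)))
}

# stack-based flood fill connected-component labeling (6/18/26 neighborhood)
floodFillLabel <- function(selected, connectivity = 6) {
  d <- dim(selected)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, ],
                 "18" = offs[rowSums(abs(offs)) <= 2, ],
                 "26" = offs)
  lab <- array(0L, d)
  nextLab <- 0L
  for (start in which(selected)) {
    if (lab[start] > 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    lab[start] <- nextLab
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ai <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ai + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (selected[li] && lab[li] == 0L) {
          lab[li] <- nextLab
          stack <- c(stack, li)
        }
      }
    }
  }
  lab
}

# canonical relabeling so partitions can be compared across labelers
canonicalLabels <- function(lab) {
  v <- lab[lab > 0]
  match(v, unique(v))
}

mkProfile <- function(y, coords = seq_along(y), region = "test") {
  new("AxisProfile", region = region, axis = 2L, method = "peak",
      coordinates = as.numeric(coords), meanScale = as.numeric(y),
      nVoxels = rep(1L, length(y)))
}

# subjects x 6 beta map stack on a tiny grid from per-voxel tuning curves
mkBetaMap <- function(centers, dim3, amplitude = 1, width = 1, noiseSd = 0) {
  B <- amplitude * exp(-outer(centers, 1:6, "-")^2 / (2 * width^2))
  if (noiseSd > 0) B <- B + matrix(rnorm(length(B), 0, noiseSd), nrow(B))
  new("ScaleBetaMap", betas = array(B, c(dim3, 6)), voxelSizeMm = 3)
}

# one simulated run + GLM fit for closed-loop tests
closedLoopBetas <- function(dim3, nRuns = 1, seed = 1, jitterSd = 0.2,
                            noise = noiseSpec(ar = numeric(0), innovationSd = 0,
                                              driftAmplitude = 0, baseline = 1000)) {
  p <- generateParadigm(nRuns, 24, 2.5, seed = seed)
  f <- generateTuningField(dim = dim3, mask = array(TRUE, dim3),
                           jitterSd = jitterSd, seed = seed + 1)
  sim <- simulateBold(p, f, noise, seed = seed + 2)
  Y <- do.call(rbind, lapply(sim$runs, function(a)
    percentSignalChange(t(matrix(a, prod(dim3), dim(a)[4])))))
  fit <- fitGlmAR2(Y, sim$design)
  list(betas = fit@betas[, paste0("scale", 1:6), drop = FALSE],
       truth = sim$trueResponse, fit = fit, sim = sim, paradigm = p, field = f)
}
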