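test_that("HRF kernel has the canonical shape and samples consistently", {
  h <- hrfKernel(0.1)
  t <- attr(h, "times")
  expect_equal(t[which.max(h)], 5, tolerance = 0.11)  # mode of gamma(6,1)
  expect_gt(sum(h), 0)

  hc <- hrfKernel(2.5)
  fineIdx <- match(attr(hc, "times"), t)
  expect_equal(as.numeric(hc), as.numeric(h)[fineIdx], tolerance = 1e-12)

  h0 <- hrfKernel(0.1, undershootRatio = 0)
  expect_true(all(h0 >= 0))

  expect_error(hrfKernel(0), "positive")
  expect_error(hrfKernel(-1), "positive")
})

test_that("design columns match a brute-force convolution oracle", {
  blocksDf <- data.frame(run = 1L, onset = 10, duration = 12.5, scale = 3L,
                         location = 5L, task = "spatial")
  p <- new("Paradigm", blocks = blocksDf, trSeconds = 2.5,
           volumesPerRun = 40L, nRuns = 1L)
  des <- buildDesignMatrix(p)
  X <- designMatrix(des)

  h <- hrfKernel(0.1)
  tFine <- seq(0, 100 + 1e-9, by = 0.1)
  box <- as.numeric(tFine >= 10 - 1e-9 & tFine < 22.5 - 1e-9)
  oracle <- oracleConvolve(box, as.numeric(h), 0.1)
  volIdx <- round((0:39) * 2.5 / 0.1) + 1
  expect_equal(X[, "scale3"], oracle[volIdx], tolerance = 1e-8)
  expect_equal(which.max(X[, "scale3"]), which.max(oracle[volIdx]))

  # scales with no blocks give identically zero columns
  for (s in c(1, 2, 4, 5, 6)) expect_true(all(X[, paste0("scale", s)] == 0))

  # linearity: two non-overlapping blocks = sum of single-block columns
  b2 <- rbind(blocksDf, data.frame(run = 1L, onset = 50, duration = 12.5,
                                   scale = 3L, location = 5L, task = "spatial"))
  p2 <- new("Paradigm", blocks = b2, trSeconds = 2.5, volumesPerRun = 40L,
            nRuns = 1L)
  pb <- new("Paradigm", blocks = b2[2, ], trSeconds = 2.5, volumesPerRun = 40L,
            nRuns = 1L)
  expect_equal(designMatrix(buildDesignMatrix(p2))[, "scale3"],
               X[, "scale3"] + designMatrix(buildDesignMatrix(pb))[, "scale3"],
               tolerance = 1e-12)

  # block outside the acquisition window is rejected naming the block
  bBad <- data.frame(run = 1L, onset = 95, duration = 12.5, scale = 1L,
                     location = 1L, task = "spatial")
  expect_error(new("Paradigm", blocks = bBad, trSeconds = 2.5,
                   volumesPerRun = 40L, nRuns = 1L), "window")

  expect_error(buildDesignMatrix(p, nuisance = matrix(0, 10, 2)), "volumes")
})

test_that("all convolved columns agree with the oracle on a full paradigm", {
  p <- generateParadigm(1, 12, 2.5, seed = 3)
  X <- designMatrix(buildDesignMatrix(p))
  h <- hrfKernel(0.1)
  nVol <- volumesPerRun(p)
  tFine <- seq(0, nVol * 2.5 + 1e-9, by = 0.1)
  volIdx <- round((seq_len(nVol) - 1) * 2.5 / 0.1) + 1
  b <- blocks(p)
  for (s in 1:6) {
    bs <- b[b$scale == s, ]
    box <- numeric(length(tFine))
    for (i in seq_len(nrow(bs)))
      box[tFine >= bs$onset[i] - 1e-9 & tFine < bs$onset[i] + 12.5 - 1e-9] <- 1
    oracle <- oracleConvolve(box, as.numeric(h), 0.1)[volIdx]
    expect_equal(X[, paste0("scale", s)], oracle, tolerance = 1e-8)
  }
})

test_that("percent signal change scales and excludes per contract", {
  expect_true(all(percentSignalChange(rep(200, 10)) == 0))
  expect_equal(as.numeric(percentSignalChange(c(90, 110))), c(-10, 10))
  out <- percentSignalChange(cbind(c(90, 110), c(0, 0)))
  expect_true(all(is.na(out[, 2])))
  expect_identical(attr(out, "excluded"), c(FALSE, TRUE))
  # no exception for a zero-mean voxel
  expect_silent(percentSignalChange(c(-1, 1)))
})

test_that("the AR(2) GLM recovers betas, AR coefficients and absorbs offsets", {
  cl <- closedLoopBetas(c(3L, 4L, 3L), seed = 2)
  relErr <- abs(cl$betas - cl$truth) / pmax(abs(cl$truth), 1e-12)
  expect_lt(max(relErr), 1e-6)

  # intercept absorption: adding a constant leaves betas unchanged
  d <- c(2L, 2L, 1L)
  p <- generateParadigm(1, 12, 2.5, seed = 4)
  f <- generateTuningField(dim = d, mask = array(TRUE, d), jitterSd = 0, seed = 1)
  ns <- noiseSpec(ar = c(0.3, 0.2), innovationSd = 1, driftAmplitude = 0,
                  baseline = 1000)
  sim <- simulateBold(p, f, ns, seed = 5)
  Y <- percentSignalChange(t(matrix(sim$runs[[1]], prod(d),
                                    volumesPerRun(p))))
  f1 <- fitGlmAR2(Y, sim$design)
  f2 <- fitGlmAR2(Y + 5, sim$design)
  task <- paste0("scale", 1:6)
  expect_equal(f1@betas[, task], f2@betas[, task], tolerance = 1e-6)

  # AR coefficient recovery on signal-free AR(2) series
  set.seed(10)
  est <- replicate(30, {
    e <- as.numeric(stats::filter(rnorm(3000), c(0.3, 0.2),
                                  method = "recursive"))
    pp <- generateParadigm(1, 6, 2.5, seed = 1, volumesPerRun = 3000)
    fitGlmAR2(matrix(e, ncol = 1), buildDesignMatrix(pp))@arCoefficients
  })
  expect_lt(abs(mean(est[1, 1, ]) - 0.3), 0.05)
  expect_lt(abs(mean(est[1, 2, ]) - 0.2), 0.05)

  # rank-deficient design is rejected with the collinear columns named
  b1 <- blocks(generateParadigm(1, 6, 2.5, seed = 1))
  pr <- new("Paradigm", blocks = b1, trSeconds = 2.5, volumesPerRun = 200L,
            nRuns = 1L)
  dupNuis <- designMatrix(buildDesignMatrix(pr))[, "scale1", drop = FALSE]
  colnames(dupNuis) <- "dup"
  desBad <- buildDesignMatrix(pr, nuisance = dupNuis)
  expect_error(fitGlmAR2(matrix(rnorm(200), ncol = 1), desBad),
               "rank deficient.*dup")
})

test_that("beta estimates are unbiased under AR(2) noise (property)", {
  d <- c(2L, 2L, 1L)
  p <- generateParadigm(1, 12, 2.5, seed = 4)
  f <- generateTuningField(dim = d, mask = array(TRUE, d), jitterSd = 0, seed = 1)
  ns <- noiseSpec(ar = c(0.3, 0.2), innovationSd = 10, driftAmplitude = 0,
                  baseline = 1000)
  task <- paste0("scale", 1:6)
  errs <- sapply(1:200, function(i) {
    sim <- simulateBold(p, f, ns, seed = 100 + i)
    Y <- percentSignalChange(t(matrix(sim$runs[[1]], prod(d),
                                      volumesPerRun(p))))
    fit <- fitGlmAR2(Y, sim$design, arMethod = "pooled")
    (fit@betas[, task] - sim$trueResponse)[1, ]
  })
  meanErr <- rowMeans(errs)
  seMean <- apply(errs, 1, sd) / sqrt(ncol(errs))
  expect_true(all(abs(meanErr) < 2 * seMean + 1e-8))
})

test_that("AR(2) whitening calibrates the beta t-test better than OLS", {
  # null simulations: no signal, AR(2) noise; reject when |t| > t_crit
  p <- generateParadigm(1, 6, 2.5, seed = 1, volumesPerRun = 120)
  des <- buildDesignMatrix(p)
  set.seed(77)
  rej <- replicate(500, {
    e <- as.numeric(stats::filter(rnorm(120, 0, 1), c(0.45, 0.3),
                                  method = "recursive"))
    y <- matrix(e, ncol = 1)
    fw <- fitGlmAR2(y, des, whiten = TRUE)
    fo <- fitGlmAR2(y, des, whiten = FALSE)
    tw <- fw@betas[1, "scale1"] / fw@se[1, "scale1"]
    to <- fo@betas[1, "scale1"] / fo@se[1, "scale1"]
    c(abs(tw) > qt(0.975, fw@df), abs(to) > qt(0.975, fo@df))
  })
  typeI <- rowMeans(rej)
  expect_lt(abs(typeI[1] - 0.05), abs(typeI[2] - 0.05))
})

test_that("group random effects and contrasts follow the t-statistic contract", {
  mk <- function(v) new("ScaleBetaMap",
                        betas = array(rep(v, 6), c(1, 1, 1, 6)),
                        voxelSizeMm = 3)
  g <- groupRandomEffects(list(mk(1), mk(2), mk(3)))
  expect_equal(g@mean[1, 1, 1, 1], 2)
  expect_equal(g@se[1, 1, 1, 1], sd(1:3) / sqrt(3))
  expect_equal(g@t[1, 1, 1, 1], 2 / (sd(1:3) / sqrt(3)), tolerance = 1e-12)
  expect_equal(g@t[1, 1, 1, 1], 3.464, tolerance = 1e-3)

  gSame <- groupRandomEffects(list(mk(2), mk(2), mk(2)))
  expect_true(all(is.na(gSame@t)))

  maps <- list(mk(1), mk(4), mk(2))
  expect_equal(groupRandomEffects(maps)@mean,
               groupRandomEffects(rev(maps))@mean)
  expect_error(groupRandomEffects(list(mk(1))), ">= 2")

  # paired contrast, hand-computed: diffs (0.5, 1, 1.5, 2) -> t = 3.873
  sb <- cbind(c(1, 2, 3, 4), c(0.5, 1.0, 1.5, 2.0))
  res <- contrastBetas(sb, c(1, -1))
  expect_equal(res$t, 1.25 / (sd(c(0.5, 1, 1.5, 2)) / 2), tolerance = 1e-12)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_error(contrastBetas(sb, c(0, 0)), "zero")
  resDeg <- contrastBetas(cbind(1:4, (1:4) - 1), c(1, -1))
  expect_true(is.na(resDeg$t))
})

test_that("modulation regressors follow ratings and the convolution oracle", {
  p <- generateParadigm(1, 12, 2.5, seed = 2)
  r <- generateRatings(nSubjects = 2, seed = 1)

  # all ratings equal -> z-transform zero -> regressor identically zero
  rFlat <- r
  rFlat@locationRatings$familiarity <- 4
  expect_true(all(buildModulationRegressor(p, rFlat, "familiarity",
                                           subject = 1) == 0))

  # per-block values: column matches the direct convolution oracle
  sp <- blocks(p)
  vals <- rnorm(nrow(sp))
  reg <- buildModulationRegressor(p, values = vals, measure = "rt")
  z <- (vals - mean(vals)) / sd(vals)
  h <- hrfKernel(0.1)
  nVol <- volumesPerRun(p)
  tFine <- seq(0, nVol * 2.5 + 1e-9, by = 0.1)
  x <- numeric(length(tFine))
  for (i in seq_len(nrow(sp)))
    x[tFine >= sp$onset[i] - 1e-9 & tFine < sp$onset[i] + 12.5 - 1e-9] <- z[i]
  oracle <- oracleConvolve(x, as.numeric(h), 0.1)[round((seq_len(nVol) - 1) *
                                                          2.5 / 0.1) + 1]
  expect_equal(as.numeric(reg), oracle - mean(oracle), tolerance = 1e-8)

  # missing rating is rejected naming the block
  rMiss <- r
  rMiss@locationRatings <- rMiss@locationRatings[
    !(rMiss@locationRatings$subject == 1 & rMiss@locationRatings$location == 3), ]
  expect_error(buildModulationRegressor(p, rMiss, "familiarity", subject = 1),
               "no 'familiarity' rating for block")
})
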