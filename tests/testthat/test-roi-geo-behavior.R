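test_that("ROI betas summarize subject means with correct SE", {
  d <- c(3L, 3L, 1L)
  m1 <- mkBetaMap(rep(2, prod(d)), d)
  m2 <- mkBetaMap(rep(4, prod(d)), d)

  # one-voxel mask equals that voxel's group stats
  mask1 <- array(FALSE, d); mask1[2, 2, 1] <- TRUE
  s1 <- roiBetas(list(m1, m2), mask1)
  g <- groupRandomEffects(list(m1, m2))
  expect_equal(s1$mean, g@mean[2, 2, 1, ])
  expect_equal(s1$se, g@se[2, 2, 1, ])

  # hand computation: region means 1 and 3 -> group mean 2, SE 1
  mk <- function(v) new("ScaleBetaMap", betas = array(v, c(d, 6)),
                        voxelSizeMm = 3)
  s2 <- roiBetas(list(mk(1), mk(3)), array(TRUE, d))
  expect_equal(unname(s2$mean), rep(2, 6))
  expect_equal(unname(s2$se), rep(1, 6))

  # subject order invariance and linearity
  s3 <- roiBetas(list(m2, m1), mask1)
  expect_equal(sort(s1$subjectMeans[, 1]), sort(s3$subjectMeans[, 1]))
  expect_error(roiBetas(list(m1), array(FALSE, d)), "intersect")
})

test_that("event-related averages align to acquisitions and track tuning", {
  d <- c(2L, 2L, 1L)
  p <- generateParadigm(1, 6, 2.5, seed = 2)
  mask <- array(TRUE, d)

  # constant signal -> flat zero curves after PSC
  flat <- array(500, c(d, volumesPerRun(p)))
  pscFlat <- percentSignalChange(aperm(array(flat, c(d, volumesPerRun(p))),
                                       c(1, 2, 3, 4)))
  era0 <- eventRelatedAverage(list(array(0, c(d, volumesPerRun(p)))), p, mask)
  expect_true(all(era0 == 0))
  expect_equal(ncol(era0), 10)  # 10 volumes = 25 s at TR 2.5

  # noiseless tuned voxel: preferred-scale curve peaks where the convolved
  # boxcar predicts
  f <- generateTuningField(dim = d, mask = mask, slope = 0, intercept = 3,
                           jitterSd = 0, seed = 1)
  ns <- noiseSpec(ar = numeric(0), innovationSd = 0, driftAmplitude = 0,
                  baseline = 1000)
  sim <- simulateBold(p, f, ns, seed = 1)
  psc <- array(t(percentSignalChange(t(matrix(sim$runs[[1]], prod(d),
                                              volumesPerRun(p))))),
               c(d, volumesPerRun(p)))
  era <- eventRelatedAverage(list(psc), p, mask)
  expect_equal(unname(which.max(rowMeans(era))), 3)  # scale 3 preferred
  # oracle: average the convolved scale-3 predictor over the same windows
  X <- designMatrix(sim$design)[, "scale3"]
  Xc <- X - mean(X)
  b <- blocks(p); b3 <- b[b$scale == 3, ]
  win <- sapply(seq_len(nrow(b3)), function(i) {
    v0 <- ceiling(b3$onset[i] / 2.5 - 1e-9) + 1
    Xc[v0:(v0 + 9)]
  })
  expect_equal(unname(which.max(era[3, ])), unname(which.max(rowMeans(win))))

  # truncated final block is dropped with a warning
  pShort <- new("Paradigm", blocks = blocks(p), trSeconds = 2.5,
                volumesPerRun = volumesPerRun(p), nRuns = 1L)
  shortRun <- psc[, , , 1:(volumesPerRun(p) - 15), drop = FALSE]
  expect_warning(eventRelatedAverage(list(shortRun), pShort, mask),
                 "dropped")
})

test_that("network overlap percentages match brute-force counting", {
  d <- c(4L, 4L, 2L)
  parc <- array(0L, d)
  parc[1:2, , ] <- 1L; parc[3:4, , ] <- 3L

  region <- array(FALSE, d); region[3:4, 1:2, 1] <- TRUE
  ov <- networkOverlap(region, parc)
  expect_equal(ov$overlap$percent[ov$overlap$label == 3], 100)

  region2 <- array(FALSE, d); region2[2:3, 1, 1] <- TRUE
  region2[2, 2, 1] <- TRUE; region2[3, 2, 1] <- TRUE
  ov2 <- networkOverlap(region2, parc)
  expect_equal(sort(ov2$overlap$percent), c(50, 50))

  set.seed(3)
  region3 <- array(runif(prod(d)) < 0.4, d)
  region3[1, 1, 1] <- TRUE
  ov3 <- networkOverlap(region3, parc)
  for (k in seq_len(nrow(ov3$overlap))) {
    l <- ov3$overlap$label[k]
    expect_equal(ov3$overlap$percent[k],
                 100 * sum(parc[region3] == l) / sum(region3))
  }
  expect_equal(sum(ov3$overlap$percent) + ov3$unassignedPercent, 100)
  expect_error(networkOverlap(array(TRUE, c(2, 2, 2)), parc), "match")
})

test_that("haversine distances honour spherical geometry", {
  expect_equal(haversineKm(10, 20, 10, 20), 0)
  expect_equal(haversineKm(0, 0, 0, 180), pi * 6371, tolerance = 1e-12)
  expect_equal(haversineKm(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-9)
  # symmetry and longitude wrap invariance
  expect_equal(haversineKm(12, 34, -45, 100), haversineKm(-45, 100, 12, 34))
  expect_equal(haversineKm(12, 34, -45, 100), haversineKm(12, 34 - 360, -45, 100),
               tolerance = 1e-9)
  expect_error(haversineKm(91, 0, 0, 0), "latitude")

  # oracle agreement on random pairs (small version of the large check)
  set.seed(5)
  la1 <- runif(200, -89, 89); lo1 <- runif(200, -180, 180)
  la2 <- runif(200, -89, 89); lo2 <- runif(200, -180, 180)
  dH <- haversineKm(la1, lo1, la2, lo2)
  dC <- lawOfCosinesKm(la1, lo1, la2, lo2)
  expect_lt(max(abs(dH - dC) / dC), 1e-9)
})

test_that("pairwise distances cover all unordered pairs", {
  g <- generateGeoStimuli(itemsPerLocation = 8, seed = 2)
  d <- pairwiseGeoDistances(g)
  perLoc <- table(d$location)
  expect_true(all(perLoc == 28))  # choose(8, 2)

  co <- data.frame(scale = 3, location = "x", item = c("a", "b"),
                   lat = c(10, 10), lon = c(20, 20))
  expect_equal(pairwiseGeoDistances(co)$distanceKm, 0)

  single <- data.frame(scale = 3, location = c("x", "x", "y"),
                       item = c("a", "b", "c"),
                       lat = c(1, 2, 3), lon = c(1, 2, 3))
  expect_warning(out <- pairwiseGeoDistances(single), "single item")
  expect_equal(nrow(out), 1)
})

test_that("log-linear scale fit matches exact and simulated inputs", {
  exact <- data.frame(scale = rep(3:6, each = 2),
                      distanceKm = rep(c(10, 100, 1000, 10000), each = 2))
  fit <- logScaleFit(exact)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  withZero <- rbind(exact, data.frame(scale = 3, distanceKm = 0))
  fitZ <- logScaleFit(withZero)
  expect_equal(fitZ$nZeroExcluded, 1)

  two <- exact[exact$scale %in% c(3, 4), ]
  fit2 <- logScaleFit(two)
  expect_true(fit2$underdetermined)

  expect_error(logScaleFit(data.frame(scale = 3, distanceKm = 5)), ">= 2")
})

test_that("z-transform uses the sample SD and flags degenerate input", {
  z <- zTransformWithinSubject(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_false(attr(z, "degenerate"))

  zc <- zTransformWithinSubject(rep(4, 5))
  expect_true(all(zc == 0))
  expect_true(attr(zc, "degenerate"))

  set.seed(2)
  v <- rnorm(20, 5, 2)
  zv <- zTransformWithinSubject(v)
  expect_equal(mean(zv), 0, tolerance = 1e-12)
  expect_equal(sd(zv), 1, tolerance = 1e-12)
})

test_that("rating-scale correlations behave under perfect and null signals", {
  r <- generateRatings(nSubjects = 6, seed = 3)
  # ratings equal to the scale index: r = 1 for everyone, p ~ 0
  rPerfect <- r
  rPerfect@scaleRatings$thirdPerson <- rPerfect@scaleRatings$scale
  cc <- correlateWithScale(rPerfect, "thirdPerson")
  expect_true(all(cc$perSubjectR == 1))
  expect_lt(cc$p, 1e-10)

  # constant ratings: subject excluded with count
  rConst <- r
  rConst@scaleRatings$firstPerson[rConst@scaleRatings$subject == 1] <- 4
  cc2 <- correlateWithScale(rConst, "firstPerson")
  expect_equal(cc2$nExcluded, 1)

  # positive affine transform of a subject's ratings leaves r unchanged
  rAff <- r
  i <- rAff@scaleRatings$subject == 2
  before <- correlateWithScale(rAff, "thirdPerson")$perSubjectR[2]
  rAff@scaleRatings$thirdPerson[i] <-
    0.5 * rAff@scaleRatings$thirdPerson[i] + 1
  after <- correlateWithScale(rAff, "thirdPerson")$perSubjectR[2]
  expect_equal(before, after, tolerance = 1e-12)

  # type-I error calibration under independence
  set.seed(11)
  rej <- replicate(300, {
    rr <- generateRatings(targets = c(familiarity = 0, emotion = 0,
                                      difficulty = 0, firstPerson = 0,
                                      thirdPerson = 0, mapStrategy = 0),
                          nSubjects = 10, seed = sample.int(1e6, 1))
    correlateWithScale(rr, "firstPerson")$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("scale ANOVA with Tukey-Kramer matches a studentized-range oracle", {
  r <- generateRatings(nSubjects = 8, seed = 4)
  # identical group means: F ~ 0, no pair significant
  rFlat <- r
  rFlat@scaleRatings$mapStrategy <- 4
  aFlat <- anovaScales(rFlat, "mapStrategy")
  expect_false(any(aFlat$pairs$significant))

  # two groups 10 SD apart: that pair significant
  rSep <- r
  i6 <- rSep@scaleRatings$scale == 6
  rSep@scaleRatings$mapStrategy <- 4 + rnorm(nrow(rSep@scaleRatings), 0, 0.05)
  rSep@scaleRatings$mapStrategy[i6] <- 6
  rSep@scaleRatings$mapStrategy <- pmin(7, rSep@scaleRatings$mapStrategy)
  aSep <- anovaScales(rSep, "mapStrategy")
  expect_true(aSep$pairs$significant[aSep$pairs$pair == "6-1"])

  # crafted unbalanced table vs manual Tukey-Kramer computation
  set.seed(9)
  vals <- c(rnorm(5, 0), rnorm(7, 1), rnorm(6, 3))
  grp <- rep(1:3, c(5, 7, 6))
  fit <- aov(vals ~ factor(grp))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfe <- summary(fit)[[1]]["Residuals", "Df"]
  m <- tapply(vals, grp, mean); n <- tapply(vals, grp, length)
  qstat <- abs(m[2] - m[1]) / sqrt(mse / 2 * (1 / n[1] + 1 / n[2]))
  pOracle <- ptukey(qstat, 3, dfe, lower.tail = FALSE)
  tk <- TukeyHSD(fit)$`factor(grp)`
  expect_equal(unname(tk["2-1", "p adj"]), unname(pOracle), tolerance = 1e-9)

  # group relabeling leaves the omnibus p unchanged
  a1 <- anovaScales(r, "thirdPerson")
  rRel <- r
  rRel@scaleRatings$scale <- 7 - rRel@scaleRatings$scale
  a2 <- anovaScales(rRel, "thirdPerson")
  expect_equal(a1$p, a2$p, tolerance = 1e-12)
})
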