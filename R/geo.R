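#' Great-circle distance between latitude/longitude points
#'
#' Haversine distance on a sphere,
#' d = 2 R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2))),
#' computed via [geosphere::distHaversine()]. Vectorized over point pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; latitudes must
#'   lie in [-90, 90].
#' @param radiusKm sphere radius; default 6371 km (mean Earth radius).
#' @return distance(s) in km.
#' @examples
#' haversineKm(0, 0, 0, 180)  # half circumference, pi * 6371
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2, radiusKm = 6371) {
  if (any(lat1 < -90 | lat1 > 90 | lat2 < -90 | lat2 > 90))
    stop("latitude outside [-90, 90]")
  wrap <- function(l) ((l + 180) %% 360) - 180
  geosphere::distHaversine(cbind(wrap(lon1), lat1), cbind(wrap(lon2), lat2),
                           r = radiusKm)
}

#' All pairwise item distances per location and scale
#'
#' Unordered pairs within every location (n items give n(n-1)/2 distances).
#' Locations with a single item are skipped with a warning.
#'
#' @param stimuli a [GeoStimulusSet] or data.frame with columns `scale`,
#'   `location`, `item`, `lat`, `lon`.
#' @param radiusKm sphere radius in km.
#' @return data.frame: `scale`, `location`, `item1`, `item2`, `distanceKm`.
#' @export
pairwiseGeoDistances <- function(stimuli, radiusKm = 6371) {
  e <- if (is(stimuli, "GeoStimulusSet")) geoEntries(stimuli) else stimuli
  keys <- unique(e[, c("scale", "location")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    g <- e[e$scale == keys$scale[i] & e$location == keys$location[i], ]
    n <- nrow(g)
    if (n < 2L) {
      warning(sprintf("location '%s' (scale %d) has a single item; skipped",
                      keys$location[i], keys$scale[i]))
      return(NULL)
    }
    pr <- utils::combn(n, 2L)
    data.frame(scale = keys$scale[i], location = keys$location[i],
               item1 = g$item[pr[1, ]], item2 = g$item[pr[2, ]],
               distanceKm = haversineKm(g$lat[pr[1, ]], g$lon[pr[1, ]],
                                        g$lat[pr[2, ]], g$lon[pr[2, ]],
                                        radiusKm = radiusKm))
  })
  do.call(rbind, out)
}

#' Log-linear fit of environment size on spatial scale
#'
#' Least-squares line of log10 pairwise distance on the scale index.
#' Zero distances cannot be logged; they are excluded and counted.
#'
#' @param distances data.frame from [pairwiseGeoDistances()] (needs columns
#'   `scale` and `distanceKm`).
#' @param aggregate "meanLog" (default) fits per-scale means of log10
#'   distance; "logMean" fits log10 of per-scale mean distance; "perPair"
#'   fits every pair's log10 distance.
#' @return list: `perScale` (data.frame scale/meanLog10Km/nPairs/nZero),
#'   `slope`, `intercept`, `r2`, `nZeroExcluded`, `aggregate`,
#'   `underdetermined` (TRUE with only 2 scales).
#' @export
logScaleFit <- function(distances, aggregate = c("meanLog", "logMean",
                                                 "perPair")) {
  aggregate <- match.arg(aggregate)
  d <- distances[, c("scale", "distanceKm")]
  zero <- d$distanceKm <= 0
  nZero <- sum(zero)
  d <- d[!zero, , drop = FALSE]
  scales <- sort(unique(d$scale))
  if (length(scales) < 2L)
    stop("need >= 2 scales with positive distances")
  perScale <- do.call(rbind, lapply(scales, function(s) {
    x <- d$distanceKm[d$scale == s]
    data.frame(scale = s, meanLog10Km = mean(log10(x)),
               log10MeanKm = log10(mean(x)), nPairs = length(x),
               nZero = sum(distances$scale == s & zero))
  }))
  fitDat <- switch(aggregate,
    meanLog = data.frame(x = perScale$scale, y = perScale$meanLog10Km),
    logMean = data.frame(x = perScale$scale, y = perScale$log10MeanKm),
    perPair = data.frame(x = d$scale, y = log10(d$distanceKm)))
  fit <- stats::lm(y ~ x, data = fitDat)
  # r2 computed directly; summary.lm warns on numerically perfect fits
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((fitDat$y - mean(fitDat$y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  list(perScale = perScale, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = r2,
       nZeroExcluded = nZero, aggregate = aggregate,
       underdetermined = length(scales) == 2L && aggregate != "perPair")
}
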