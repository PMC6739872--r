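#' Within-subject z-transform
#'
#' Standardizes a subject's ratings to mean 0, SD 1 using the sample (n-1)
#' standard deviation. A zero-variance vector returns zeros with attribute
#' `degenerate = TRUE` instead of failing.
#'
#' @param values numeric vector of one subject's ratings.
#' @return standardized vector (attribute `degenerate` flags zero variance).
#' @export
zTransformWithinSubject <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - mean(values)) / s
  attr(out, "degenerate") <- FALSE
  out
}

measureTable <- function(ratings, measure) {
  locMeasures <- c("familiarity", "emotion", "difficulty")
  sclMeasures <- c("firstPerson", "thirdPerson", "mapStrategy")
  if (measure %in% locMeasures) {
    tab <- ratings@locationRatings
    # scale-mean per subject: average the two locations at each scale
    agg <- stats::aggregate(tab[[measure]],
                            by = list(subject = tab$subject, scale = tab$scale),
                            FUN = mean)
    names(agg)[3] <- "value"
    agg
  } else if (measure %in% sclMeasures) {
    tab <- ratings@scaleRatings
    data.frame(subject = tab$subject, scale = tab$scale,
               value = tab[[measure]])
  } else stop(sprintf("unknown measure '%s'", measure))
}

#' Correlation of a rating measure with spatial scale
#'
#' Pearson correlation of the measure against the numeric scale index (1-6)
#' within each subject (location-level measures are first averaged per
#' scale), followed by a two-tailed one-sample t-test of the per-subject
#' correlations against zero. Subjects with constant ratings have undefined
#' r and are excluded (counted).
#'
#' @param ratings a [RatingsTable].
#' @param measure measure name (see [generateRatings()]).
#' @return list: `measure`, `perSubjectR`, `meanR`, `t`, `df`, `p`,
#'   `nExcluded`.
#' @export
correlateWithScale <- function(ratings, measure) {
  stopifnot(is(ratings, "RatingsTable"))
  tab <- measureTable(ratings, measure)
  subs <- unique(tab$subject)
  r <- vapply(subs, function(su) {
    g <- tab[tab$subject == su, ]
    if (length(unique(g$scale)) < 2L)
      stop(sprintf("subject %s has ratings at < 2 scales", su))
    if (stats::sd(g$value) == 0) return(NA_real_)
    stats::cor(g$value, g$scale)
  }, 0)
  nExcluded <- sum(is.na(r))
  rOk <- r[!is.na(r)]
  if (length(rOk) < 2L) stop("fewer than 2 subjects with defined correlations")
  if (stats::sd(rOk) == 0) {
    # all subjects identical (e.g. r = 1 everywhere): t degenerate
    tt <- list(statistic = if (mean(rOk) == 0) NA_real_ else Inf * sign(mean(rOk)),
               parameter = length(rOk) - 1,
               p.value = if (mean(rOk) == 0) NA_real_ else 0)
  } else {
    tt <- stats::t.test(rOk, mu = 0)
  }
  list(measure = measure, perSubjectR = r, meanR = mean(rOk),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, nExcluded = nExcluded)
}

#' One-way ANOVA with Tukey-Kramer post-hoc across the six scales
#'
#' Omnibus F across scale groups (observations pooled over subjects;
#' location-level measures enter as per-subject scale means) and
#' Tukey-Kramer pairwise comparisons at `alpha` (the Kramer adjustment for
#' unbalanced groups is [stats::TukeyHSD()]'s behaviour). Scales with fewer
#' than 2 observations are excluded with a warning.
#'
#' @param ratings a [RatingsTable].
#' @param measure measure name.
#' @param alpha pairwise significance level (study value 0.01).
#' @return list: `F`, `df`, `p`, `pairs` (data.frame: pair, diff, lwr, upr,
#'   pAdj, significant), `alpha`, `excludedScales`.
#' @export
anovaScales <- function(ratings, measure, alpha = 0.01) {
  stopifnot(is(ratings, "RatingsTable"))
  tab <- measureTable(ratings, measure)
  cnt <- table(tab$scale)
  drop <- as.integer(names(cnt)[cnt < 2L])
  if (length(drop)) {
    warning(sprintf("scale(s) %s excluded (< 2 observations)",
                    paste(drop, collapse = ", ")))
    tab <- tab[!tab$scale %in% drop, ]
  }
  if (length(unique(tab$scale)) < 2L) stop("need >= 2 scales with >= 2 observations")
  tab$scale <- factor(tab$scale)
  fit <- stats::aov(value ~ scale, data = tab)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$scale
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      pAdj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = an[["F value"]][1], df = an[["Df"]],
       p = an[["Pr(>F)"]][1], pairs = pairs, alpha = alpha,
       excludedScales = drop)
}
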