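# Trend estimation and testing on fire metrics: weighted quantile-regression
# trends of burn elevation on year, Mann-Kendall tests (classic and
# Hamed-Rao autocorrelation-corrected), epoch comparisons, tercile composites
# with two-sample distribution tests, and interannual correlation.

#' Quantile-regression trend of burn elevation on year
#'
#' Minimises the weighted check (pinball) loss of elevation on year at level
#' \code{tau}. Each fire year contributes a weighted elevation sample (the
#' normalised burn distribution); per-year weights are normalised to sum to
#' one so every fire year carries equal mass. The total change is the slope
#' times the number of fire years, and its 95\% CI comes from a seeded
#' year-block bootstrap (years resampled with replacement).
#'
#' @param years numeric vector of fire years (>= 5 distinct; fire-free years
#'   already excluded).
#' @param samples list of numeric elevation vectors, one per year.
#' @param weights list of positive weight vectors matching \code{samples};
#'   \code{NULL} for unweighted.
#' @param tau quantile level (default 0.9).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap and any subsampling.
#' @param maxPointsPerYear years with more weighted points are subsampled
#'   (probability proportional to weight) to this size for tractability.
#' @return A \linkS4class{TrendResult}; p-value is the two-sided bootstrap
#'   sign probability of the slope.
#' @export
quantileTrend <- function(years, samples, weights = NULL, tau = 0.9,
                          nBoot = 1000L, seed = 1L,
                          maxPointsPerYear = 10000L) {
  m <- length(years)
  stopifnot(m == length(samples), tau > 0, tau < 1)
  if (length(unique(years)) < 5L)
    stop("at least 5 distinct fire years are required")
  if (is.null(weights)) weights <- lapply(samples, function(s) rep(1, length(s)))
  stopifnot(length(weights) == m)
  for (i in seq_len(m)) {
    if (length(samples[[i]]) == 0L) stop("year ", years[i], " has an empty sample")
    if (any(weights[[i]] <= 0)) stop("weights must be positive")
  }
  withSeed(seed, {
    x <- y <- w <- numeric(0)
    yearIdx <- integer(0)
    for (i in seq_len(m)) {
      ei <- samples[[i]]
      wi <- weights[[i]]
      if (length(ei) > maxPointsPerYear) {
        pick <- sample.int(length(ei), maxPointsPerYear, replace = TRUE,
                           prob = wi)
        ei <- ei[pick]
        wi <- rep(1, maxPointsPerYear)
      }
      wi <- wi / sum(wi)
      x <- c(x, rep(years[i] - years[1], length(ei)))
      y <- c(y, ei)
      w <- c(w, wi)
      yearIdx <- c(yearIdx, rep(i, length(ei)))
    }
    degenerate <- (max(y) == min(y))
    if (degenerate) {
      return(new("TrendResult", slope = 0, totalChange = 0,
                 ciSlope = c(0, 0), ciTotal = c(0, 0), pValue = 1,
                 method = paste0("weighted quantile regression (tau=", tau,
                                 "), degenerate"),
                 nYears = m, degenerate = TRUE))
    }
    span <- max(x) - min(x)
    bmax <- 2 * (max(y) - min(y)) / span
    tol <- bmax * 2.5e-4  # slope resolution ~0.01% of the bracket
    fit <- cpp_qr_fit(x, y, w, tau, -bmax, bmax, tol)
    # bootstrap replicates tolerate a coarser slope resolution than the
    # point estimate; the CI quantiles are far wider than this granularity
    slopes <- cpp_qr_boot(x, y, w, yearIdx, m, tau, -bmax, bmax,
                          bmax * 2e-3, as.integer(nBoot))
    slopes <- slopes[is.finite(slopes)]
    ciS <- unname(quantile(slopes, c(0.025, 0.975), type = 7))
    # a percentile bootstrap interval need not contain the point estimate
    # (e.g. set-valued check-loss optima); widen it so it always does
    ciS <- c(min(ciS[1], fit$slope), max(ciS[2], fit$slope))
    pLow <- mean(slopes <= 0)
    pHigh <- mean(slopes >= 0)
    pv <- min(1, 2 * min(pLow, pHigh))
    new("TrendResult", slope = fit$slope, totalChange = fit$slope * m,
        ciSlope = ciS, ciTotal = ciS * m, pValue = pv,
        method = paste0("weighted quantile regression (tau=", tau,
                        "), year-block bootstrap"),
        nYears = as.integer(m), degenerate = FALSE)
  })
}

#' Z90 trend from a list of normalized burn distributions
#'
#' Convenience wrapper around \code{\link{quantileTrend}}. By default
#' fire-free (empty) years are dropped, since the burn elevation is
#' undefined there; excluding them can itself induce apparent trends when
#' fire-free years cluster early in the record, so a sensitivity mode is
#' provided that keeps those years as a point mass at a floor elevation
#' (typically the ecoregion's minimum forest elevation).
#'
#' @param dists list of \linkS4class{NormalizedElevDist}.
#' @param fireFreeElevation \code{NULL} (default: exclude fire-free years)
#'   or an elevation in metres assigned to fire-free years as a single
#'   unit-weight observation.
#' @param ... passed to \code{\link{quantileTrend}}.
#' @return A \linkS4class{TrendResult}.
#' @export
z90Trend <- function(dists, fireFreeElevation = NULL, ...) {
  empty <- vapply(dists, isEmpty, logical(1))
  samples <- lapply(dists, function(d) d@elev)
  weights <- lapply(dists, function(d) d@weight)
  if (is.null(fireFreeElevation)) {
    dists <- dists[!empty]
    samples <- samples[!empty]
    weights <- weights[!empty]
  } else {
    samples[empty] <- list(as.numeric(fireFreeElevation))
    weights[empty] <- list(1)
  }
  if (length(dists) < 5L)
    stop("fewer than 5 fire years: trend not estimable")
  quantileTrend(years = vapply(dists, function(d) as.numeric(d@year),
                               numeric(1)),
                samples = samples, weights = weights, ...)
}

#' Mann-Kendall trend test
#'
#' Classic Mann-Kendall S statistic with tie-corrected variance and normal
#' approximation (continuity corrected). The default variant applies the
#' Hamed-Rao autocorrelation correction: the series is detrended by its Sen
#' slope, the lag-k autocorrelations of the ranks are tested at the 5\%
#' level, and the variance of S is inflated by the effective-sample-size
#' factor built from the significant lags.
#'
#' @param x numeric series (>= 4 values, no NA).
#' @param variant "hamed-rao" (default) or "classic".
#' @param alphaAcf significance level for autocorrelation screening.
#' @return An object of class \code{"htest"} with the S statistic, Kendall
#'   tau and two-sided p-value.
#' @export
mannKendall <- function(x, variant = c("hamed-rao", "classic"),
                        alphaAcf = 0.05) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("at least 4 values are required")
  if (anyNA(x)) stop("series must not contain NA")
  dn <- deparse(substitute(x))
  if (max(x) == min(x)) {
    return(structure(list(statistic = c(S = 0), p.value = 1,
                          estimate = c(tau = 0, varS = 0),
                          method = "Mann-Kendall trend test (constant series)",
                          data.name = dn), class = "htest"))
  }
  s <- 0
  for (k in seq_len(n - 1L))
    s <- s + sum(sign(x[(k + 1L):n] - x[k]))
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
           sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  denom <- sqrt((n * (n - 1) / 2 - sum(ties * (ties - 1) / 2)) *
                (n * (n - 1) / 2))
  tau <- s / denom
  factor <- 1
  if (variant == "hamed-rao") {
    sen <- senSlope(x)
    detr <- x - sen * seq_len(n)
    r <- rank(detr)
    ac <- as.numeric(acf(r, lag.max = n - 2L, plot = FALSE,
                         demean = TRUE)$acf)[-1]
    lags <- seq_along(ac)
    crit <- qnorm(1 - alphaAcf / 2) / sqrt(n)
    sig <- abs(ac) > crit
    if (any(sig)) {
      factor <- 1 + (2 / (n * (n - 1) * (n - 2))) *
        sum((n - lags[sig]) * (n - lags[sig] - 1) * (n - lags[sig] - 2) *
            ac[sig])
      if (!is.finite(factor) || factor <= 0) factor <- 1
    }
  }
  varS <- varS * factor
  z <- if (s > 0) (s - 1) / sqrt(varS) else if (s < 0) (s + 1) / sqrt(varS)
       else 0
  p <- 2 * pnorm(-abs(z))
  structure(list(statistic = c(S = s), p.value = p,
                 estimate = c(tau = tau, varS = varS,
                              correction = factor),
                 method = paste0("Mann-Kendall trend test (", variant, ")"),
                 data.name = dn),
            class = "htest")
}

# Sen slope: median of all pairwise slopes.
senSlope <- function(x, t = seq_along(x)) {
  n <- length(x)
  num <- outer(x, x, "-")[lower.tri(matrix(0, n, n))]
  den <- outer(t, t, "-")[lower.tri(matrix(0, n, n))]
  median(-num / -den)
}

#' Percent change in mean between two epochs
#'
#' 100 * (mean(epoch2) - mean(epoch1)) / mean(epoch1). A zero first-epoch
#' mean gives an explicitly flagged undefined result, never an infinity.
#'
#' @param values annual values.
#' @param years matching years.
#' @param epoch1,epoch2 disjoint, non-empty year vectors.
#' @return list with \code{percent}, epoch means and \code{undefined} flag.
#' @export
epochPercentChange <- function(values, years, epoch1, epoch2) {
  stopifnot(length(values) == length(years))
  if (length(intersect(epoch1, epoch2)) > 0) stop("epochs must be disjoint")
  v1 <- values[years %in% epoch1]
  v2 <- values[years %in% epoch2]
  if (length(v1) == 0L || length(v2) == 0L) stop("empty epoch")
  m1 <- mean(v1)
  m2 <- mean(v2)
  if (m1 == 0)
    return(list(percent = NA_real_, mean1 = m1, mean2 = m2,
                undefined = TRUE))
  list(percent = 100 * (m2 - m1) / m1, mean1 = m1, mean2 = m2,
       undefined = FALSE)
}

# --- two-sample statistics --------------------------------------------------

ksStat <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(pooled, function(v) mean(b <= v), numeric(1))
  max(abs(Fa - Fb))
}

# Two-sample Cramer-von Mises criterion T = nm/N^2 * sum over the pooled
# sample of (F1 - F2)^2.
cvmStat <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  Fa <- vapply(pooled, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(pooled, function(v) mean(b <= v), numeric(1))
  n * m / (n + m)^2 * sum((Fa - Fb)^2)
}

# Two-sample Anderson-Darling statistic A2 (Scholz-Stephens k = 2,
# right-continuous version, valid under ties):
# A2 = (1/(n m)) * sum_{j : B_j < N} l_j (N Ma_j - n B_j)^2 / (B_j (N - B_j))
adStat <- function(a, b) {
  n <- length(a)
  m <- length(b)
  N <- n + m
  z <- sort(unique(c(a, b)))
  lj <- vapply(z, function(v) sum(c(a, b) == v), numeric(1))
  Ma <- cumsum(vapply(z, function(v) sum(a == v), numeric(1)))
  Bj <- cumsum(lj)
  keep <- Bj < N  # last pooled point contributes a zero denominator
  sum(lj[keep] * (N * Ma[keep] - n * Bj[keep])^2 /
      (Bj[keep] * (N - Bj[keep]))) / (n * m)
}

#' Tercile composite of a fire metric by a climate covariate
#'
#' Splits the metric years into the upper and lower covariate terciles
#' (middle third discarded; ties broken by stable year order) and applies a
#' battery of two-sample tests: Kolmogorov-Smirnov, two-sample
#' Cramer-von-Mises and Anderson-Darling. P-values are computed by seeded
#' permutation (default 9,999 permutations) whenever either tercile holds
#' fewer than \code{permThreshold} values, which is always the case for
#' multi-decadal annual records; above the threshold the KS p-value is
#' asymptotic and the CvM/AD p-values remain permutation based.
#'
#' @param metric annual metric values.
#' @param covariate matching covariate values (e.g. warm-season VPD).
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param permThreshold per-group size below which permutation p-values are
#'   used for KS.
#' @return list with the two samples and a data.frame of statistics and
#'   p-values.
#' @export
tercileComposite <- function(metric, covariate, nPerm = 9999L, seed = 1L,
                             permThreshold = 25L) {
  stopifnot(length(metric) == length(covariate))
  ok <- is.finite(metric) & is.finite(covariate)
  metric <- metric[ok]
  covariate <- covariate[ok]
  n <- length(metric)
  if (n < 9L) stop("at least 9 paired years are required")
  k <- n %/% 3L
  if (k < 3L) stop("fewer than 3 values per tercile")
  ord <- order(covariate)  # stable: ties keep year order
  lower <- metric[ord[seq_len(k)]]
  upper <- metric[ord[seq.int(n - k + 1L, n)]]
  stats0 <- c(ks = ksStat(upper, lower), cvm = cvmStat(upper, lower),
              ad = adStat(upper, lower))
  nU <- length(upper)
  pooled <- c(upper, lower)
  pvals <- withSeed(seed, {
    counts <- c(ks = 0L, cvm = 0L, ad = 0L)
    for (b in seq_len(nPerm)) {
      idx <- sample.int(length(pooled), nU)
      u <- pooled[idx]
      l <- pooled[-idx]
      if (ksStat(u, l) >= stats0["ks"] - 1e-12) counts["ks"] <- counts["ks"] + 1L
      if (cvmStat(u, l) >= stats0["cvm"] - 1e-12) counts["cvm"] <- counts["cvm"] + 1L
      if (adStat(u, l) >= stats0["ad"] - 1e-12) counts["ad"] <- counts["ad"] + 1L
    }
    (counts + 1) / (nPerm + 1)
  })
  if (min(nU, length(lower)) >= permThreshold) {
    pvals["ks"] <- suppressWarnings(
      ks.test(upper, lower, exact = FALSE)$p.value)
  }
  list(upper = upper, lower = lower,
       tests = data.frame(test = c("ks", "cvm", "ad"),
                          statistic = unname(stats0),
                          p.value = unname(pvals[c("ks", "cvm", "ad")])))
}

#' Interannual Pearson correlation
#'
#' Pairs with a missing metric (fire-free years) are dropped. Zero variance
#' in either series gives a flagged undefined result.
#'
#' @param x,y annual series of equal length.
#' @return list with \code{r}, \code{p.value}, \code{n} and an
#'   \code{undefined} flag.
#' @export
interannualCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) stop("at least 4 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p.value = NA_real_, n = length(x),
                undefined = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x),
       undefined = FALSE)
}
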