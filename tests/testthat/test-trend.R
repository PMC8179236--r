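test_that("parallel-quantile data give the common slope at every tau", {
  years <- 1984:1993
  spread <- seq(-20, 20, by = 2)  # identical symmetric spread each year
  samples <- lapply(years, function(t) 1000 + 5 * (t - 1984) + spread)
  for (tau in c(0.5, 0.9)) {
    tr <- quantileTrend(years, samples, tau = tau, nBoot = 50, seed = 1)
    # the check-loss optimum is set-valued on gridded data; the flat region
    # is at most the point spacing over the year span wide
    expect_lt(abs(tr@slope - 5), 0.5)
    expect_equal(tr@totalChange, tr@slope * length(years))
  }
})

test_that("constant samples give a degenerate zero trend", {
  years <- 1:6
  samples <- lapply(years, function(t) rep(1500, 3))
  tr <- quantileTrend(years, samples, nBoot = 20, seed = 1)
  expect_true(tr@degenerate)
  expect_equal(tr@slope, 0)
  expect_equal(tr@totalChange, 0)
  expect_error(quantileTrend(1:4, lapply(1:4, function(i) rnorm(3))),
               "5 distinct")
})

test_that("the weighted fit matches a brute-force check-loss grid search", {
  set.seed(42)
  years <- 2000:2005
  samples <- lapply(years, function(t) 1200 + 8 * (t - 2000) + rnorm(4, 0, 30))
  weights <- lapply(1:6, function(i) runif(4, 0.5, 2))
  tr <- quantileTrend(years, samples, weights, tau = 0.9, nBoot = 20,
                      seed = 3)
  # oracle: exhaustive search over a fine slope/intercept grid with the same
  # per-year weight normalisation
  x <- rep(years - 2000, each = 4)
  y <- unlist(samples)
  w <- unlist(lapply(weights, function(wi) wi / sum(wi)))
  oracle <- gridSearchQR(x, y, w, 0.9,
                         slopes = seq(-20, 30, by = 0.05),
                         intercepts = seq(1100, 1350, by = 0.5))
  loss <- function(a, b) {
    u <- y - a - b * x
    sum(w * ifelse(u >= 0, 0.9 * u, -0.1 * u))
  }
  # the fitted line must be at least as good as the best grid point, and the
  # slopes must agree to the grid resolution
  aHat <- local({
    u <- sort(y - tr@slope * x)
    u[which(cumsum(w[order(y - tr@slope * x)]) >= 0.9 * sum(w))[1]]
  })
  expect_lte(loss(aHat, tr@slope), oracle$loss + 1e-9)
  expect_lt(abs(tr@slope - oracle$slope), 0.5)
})

test_that("tau = 0.5 agrees with OLS for symmetric noise", {
  set.seed(7)
  years <- 1984:2003
  samples <- lapply(years, function(t) 1000 + 3 * (t - 1984) + rnorm(20, 0, 15))
  tr <- quantileTrend(years, samples, tau = 0.5, nBoot = 200, seed = 2)
  ols <- unname(coef(lm(unlist(samples) ~ rep(years, each = 20)))[2])
  expect_gte(ols, tr@ciSlope[1])
  expect_lte(ols, tr@ciSlope[2])
})

test_that("bootstrap CIs reproduce under a fixed seed", {
  set.seed(10)
  years <- 1990:1999
  samples <- lapply(years, function(t) rnorm(6, 1500 + 2 * t, 40))
  t1 <- quantileTrend(years, samples, nBoot = 100, seed = 5)
  t2 <- quantileTrend(years, samples, nBoot = 100, seed = 5)
  expect_identical(t1@ciSlope, t2@ciSlope)
  t3 <- quantileTrend(years, samples, nBoot = 100, seed = 6)
  expect_false(identical(t1@ciSlope, t3@ciSlope))
})

test_that("Mann-Kendall S, tau and tie-corrected variance are exact", {
  inc <- 1:10
  mk <- mannKendall(inc, variant = "classic")
  expect_equal(unname(mk$statistic), 45)
  expect_equal(unname(mk$estimate["tau"]), 1)
  expect_equal(unname(mannKendall(rev(inc), variant = "classic")$estimate["tau"]),
               -1)
  # length-8 toy with ties: S by pair enumeration, variance by the textbook
  # tie-term formula
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  mk <- mannKendall(x, variant = "classic")
  expect_equal(unname(mk$statistic), bruteMKS(x))
  n <- 8
  tie <- 2  # the value 1 appears twice
  varHand <- (n * (n - 1) * (2 * n + 5) - tie * (tie - 1) * (2 * tie + 5)) / 18
  expect_equal(unname(mk$estimate["varS"]), varHand)
  cst <- mannKendall(rep(4, 6))
  expect_equal(unname(cst$estimate["tau"]), 0)
  expect_equal(cst$p.value, 1)
})

test_that("the Hamed-Rao correction tames AR(1) false positives", {
  set.seed(123)
  nRep <- 300
  rejC <- rejHR <- logical(nRep)
  for (i in seq_len(nRep)) {
    x <- as.numeric(arima.sim(list(ar = 0.5), n = 34))
    rejC[i] <- mannKendall(x, variant = "classic")$p.value < 0.05
    rejHR[i] <- mannKendall(x, variant = "hamed-rao")$p.value < 0.05
  }
  expect_lt(mean(rejHR), mean(rejC))
  expect_gt(mean(rejC), 0.10)  # classic MK is badly miscalibrated here
})

test_that("epoch percent change follows the mean ratio and flags zero bases", {
  expect_equal(epochPercentChange(c(50, 50, 100, 100), c(1, 2, 3, 4),
                                  1:2, 3:4)$percent, 100)
  expect_equal(epochPercentChange(c(7, 7, 7, 7), c(1, 2, 3, 4),
                                  1:2, 3:4)$percent, 0)
  toy <- epochPercentChange(c(2, 4, 6, 3, 6, 9), 1:6, 1:3, 4:6)
  expect_equal(toy$percent, 100 * (6 - 4) / 4)
  z <- epochPercentChange(c(0, 0, 1, 2), c(1, 2, 3, 4), 1:2, 3:4)
  expect_true(z$undefined)
  expect_true(is.na(z$percent))
  expect_error(epochPercentChange(1:4, 1:4, 1:2, 2:3), "disjoint")
})

test_that("tercile composites split correctly and the test battery behaves", {
  # complete separation: upper-tercile metric strictly above lower
  cov <- 1:15
  met <- cov * 10
  tc <- tercileComposite(met, cov, nPerm = 499, seed = 1)
  expect_equal(tc$tests$statistic[tc$tests$test == "ks"], 1)
  expect_lt(tc$tests$p.value[tc$tests$test == "ks"], 0.05)
  # identical metric everywhere: statistics minimal, permutation p ~ 1
  tc0 <- tercileComposite(rep(5, 12), rnorm(12), nPerm = 199, seed = 1)
  expect_equal(tc0$tests$statistic, rep(0, 3))
  expect_equal(tc0$tests$p.value, rep(1, 3))
  # 12-year toy: KS equals the brute-force ECDF sup-difference
  set.seed(4)
  met <- rnorm(12)
  cov <- rnorm(12)
  tc <- tercileComposite(met, cov, nPerm = 199, seed = 2)
  expect_equal(tc$tests$statistic[tc$tests$test == "ks"],
               bruteKS(tc$upper, tc$lower))
  # reproducible under a fixed seed
  tc2 <- tercileComposite(met, cov, nPerm = 199, seed = 2)
  expect_identical(tc$tests, tc2$tests)
  expect_error(tercileComposite(rnorm(8), rnorm(8)), "9 paired")
})

test_that("interannual correlation handles exact fits, NAs and zero variance", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(interannualCorrelation(x, 2 * x + 3)$r, 1, tolerance = 1e-12)
  cst <- interannualCorrelation(x, rep(2, 6))
  expect_true(cst$undefined)
  # 8-pair toy equals the hand-computed covariance ratio
  set.seed(9)
  a <- rnorm(8); b <- rnorm(8)
  r <- interannualCorrelation(a, b)
  expect_equal(r$r, cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  # fire-free (NA) pairs are dropped
  b2 <- b; b2[3] <- NA
  expect_equal(interannualCorrelation(a, b2)$n, 7)
})

test_that("fire-free years can be floored instead of excluded", {
  g <- uniformForestGrid(1000, 2000, by = 10)
  e <- elevations(g)
  dists <- lapply(1:10, function(i) {
    # fires in the first half only, climbing; later years fire-free
    burned <- if (i <= 6) abs(e - (1400 + 40 * i)) <= 100 else rep(FALSE, length(e))
    normalizedBurnDistribution(g, AnnualBurn(1989L + i, matrix(burned, 1)))
  })
  trEx <- z90Trend(dists, nBoot = 30, seed = 1)
  expect_equal(trEx@nYears, 6L)
  trFloor <- z90Trend(dists, fireFreeElevation = 1000, nBoot = 30, seed = 1)
  expect_equal(trFloor@nYears, 10L)
  # flooring late fire-free years pulls the fitted trend down
  expect_lt(trFloor@slope, trEx@slope)
})
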