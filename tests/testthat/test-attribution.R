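test_that("type I and type II sensitivities agree on exact lines", {
  vpd <- seq(1.2, 2.0, length.out = 10)
  metric <- 300 * vpd + 100
  f1 <- suppressWarnings(fitSensitivity(vpd, metric, "type1"))
  f2 <- fitSensitivity(vpd, metric, "type2")
  expect_equal(f1@slope, 300, tolerance = 1e-9)
  expect_equal(f2@slope, 300, tolerance = 1e-9)
  expect_equal(f1@r, 1, tolerance = 1e-12)
})

test_that("the SMA slope is the signed sd ratio", {
  # construct data with sd(metric)/sd(vpd) = 2 and r = -0.5 exactly
  set.seed(31)
  x <- scale(1:12)[, 1]
  z <- scale(resid(lm(rnorm(12) ~ x)))[, 1]
  y <- 2 * (-0.5 * x + sqrt(1 - 0.25) * z)
  expect_equal(sd(y) / sd(x), 2, tolerance = 1e-9)
  expect_equal(cor(x, y), -0.5, tolerance = 1e-9)
  f <- fitSensitivity(x, y, "type2")
  expect_equal(f@slope, -2, tolerance = 1e-9)
  # classic inequality: |SMA| >= |OLS| whenever |r| < 1
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(15)
    b <- 0.6 * a + rnorm(15)
    expect_gte(abs(fitSensitivity(a, b, "type2")@slope),
               abs(fitSensitivity(a, b, "type1")@slope) - 1e-12)
  }
})

test_that("the OLS sensitivity equals the normal equations on a toy table", {
  set.seed(8)
  vpd <- rnorm(8, 1.6, 0.2)
  met <- rnorm(8, 2000, 300)
  f <- fitSensitivity(vpd, met, "type1")
  hand <- sum((vpd - mean(vpd)) * (met - mean(met))) /
    sum((vpd - mean(vpd))^2)
  expect_equal(f@slope, hand, tolerance = 1e-12)
  expect_error(fitSensitivity(rep(1.5, 8), met), "variance")
  expect_error(fitSensitivity(vpd[1:4], met[1:4]), "5")
})

test_that("VPD-driven change is the slope times the VPD trend times the span", {
  years <- 1984:2017
  vpd <- 1.8 + (0.4 / 34) * (years - 1984)  # exact +0.4 kPa over 34 years
  met <- 300 * vpd + 100
  fit <- suppressWarnings(fitSensitivity(vpd, met, "type1"))
  att <- vpdDrivenChange(fit, vpd, years)
  expect_equal(att@vpdTotalChange, 0.4, tolerance = 1e-9)
  expect_equal(att@attributedChange, 120, tolerance = 1e-6)
  # zero trend gives zero attributed change
  set.seed(2)
  flat <- rep(1.8, 34)
  met2 <- rnorm(34, 50, 5)
  att0 <- vpdDrivenChange(fitSensitivity(flat + rnorm(34, 0, 0.05), met2),
                          rep(1.8, 34), years)
  expect_lt(abs(att0@attributedChange), 1e-6)
  # attribution is linear in the VPD trend
  vpd2 <- 1.8 + (0.8 / 34) * (years - 1984)
  att2 <- vpdDrivenChange(fit, vpd2, years)
  expect_equal(att2@attributedChange, 2 * att@attributedChange,
               tolerance = 1e-9)
})

test_that("percent change uses the fitted start-of-record base", {
  years <- 1984:2017
  vpd <- 1.5 + (0.3 / 34) * (years - 1984)
  fit <- new("SensitivityFit", slope = 50, intercept = 5.86 - 50 * 1.5,
             r = 0.8, pValue = 0.01, method = "type1", nYears = 34L,
             metric = "ba90")
  att <- vpdDrivenChange(fit, vpd, years)
  expect_equal(att@attributedChange, 15, tolerance = 1e-9)
  expect_equal(att@fittedStart, 5.86, tolerance = 1e-9)
  expect_equal(att@percentChange, 100 * 15 / 5.86, tolerance = 1e-9)
  # non-positive base: percent undefined, absolute change still reported
  fitNeg <- new("SensitivityFit", slope = 50, intercept = -50 * 1.5 - 1,
                r = 0.8, pValue = 0.01, method = "type1", nYears = 34L,
                metric = "ba90")
  attNeg <- vpdDrivenChange(fitNeg, vpd, years)
  expect_true(is.na(attNeg@percentChange))
  expect_equal(attNeg@attributedChange, 15, tolerance = 1e-9)
})

test_that("hypsometric exposure integrates the forest area between Z90 ends", {
  # uniform hypsometry: 50 km2 per metre over [1000, 3000]
  e <- 1000:3000
  g <- ForestGrid(e, rep(TRUE, length(e)), cellArea = 50)
  years <- 1984:2017
  # trend-line VPD evaluated at the endpoint years differs by 0.3 kPa
  vpd <- 1.5 + (0.3 / 33) * (years - 1984)
  # regression chosen so predicted Z90 goes 1500 -> 1620 m (+120 m)
  slope <- 120 / 0.3
  vStart <- 1.5  # trend-line VPD at 1984
  fit <- new("SensitivityFit", slope = slope,
             intercept = 1500 - slope * vStart, r = 0.9, pValue = 0.01,
             method = "type1", nYears = 34L, metric = "z90")
  hyp <- hypsometricExposure(g, fit, vpd, years)
  expect_equal(hyp@z90Start, 1500, tolerance = 1e-6)
  expect_equal(hyp@z90End, 1620, tolerance = 1e-6)
  expect_equal(hyp@exposedArea, 120 * 50, tolerance = 1e-6)
  expect_equal(hyp@exposedFraction, 6000 / (2001 * 50), tolerance = 1e-9)
  # zero trend exposes nothing
  fit0 <- new("SensitivityFit", slope = slope, intercept = 1500 - slope * 1.5,
              r = 0, pValue = 1, method = "type1", nYears = 34L,
              metric = "z90")
  hyp0 <- hypsometricExposure(g, fit0, rep(1.5, 34), years)
  expect_equal(hyp0@exposedArea, 0)
  # stepped hypsometry, hand-integrated: 100-m bands of 10/20/40 km2
  e2 <- c(rep(1050, 10), rep(1150, 20), rep(1250, 40))
  g2 <- ForestGrid(e2, rep(TRUE, length(e2)), cellArea = 1)
  fit2 <- new("SensitivityFit", slope = 120 / 0.3,
              intercept = 1100 - (120 / 0.3) * vStart, r = 0.9,
              pValue = 0.01, method = "type1", nYears = 34L, metric = "z90")
  hyp2 <- hypsometricExposure(g2, fit2, vpd, years)
  # 1100 -> 1220: only the 1150 band lies inside (1100, 1220]
  expect_equal(hyp2@exposedArea, 20)
  expect_false(hyp2@clamped)
  # out-of-range predictions are clamped and flagged
  fit3 <- new("SensitivityFit", slope = 1e5, intercept = 0, r = 0.9,
              pValue = 0.01, method = "type1", nYears = 34L, metric = "z90")
  hyp3 <- hypsometricExposure(g, fit3, vpd, years)
  expect_true(hyp3@clamped)
  expect_lte(hyp3@z90End, 3000)
})

test_that("ecoregion aggregation takes medians, sums and significance counts", {
  df <- data.frame(dz = c(100, 120, 300), area = c(10, 20, 30),
                   p = c(0.01, 0.2, 0.04))
  s <- aggregateEcoregions(df, medianCols = "dz", sumCols = "area",
                           pCols = "p")
  expect_equal(s$medians$dz$median, 120)
  expect_equal(s$totals$area, 60)
  expect_equal(s$nSignificant$p, 2)
  one <- aggregateEcoregions(df[2, ], medianCols = "dz", sumCols = "area")
  expect_equal(one$medians$dz$median, 120)
  expect_equal(one$totals$area, 20)
  dfNA <- data.frame(dz = c(100, NA, 300))
  sNA <- aggregateEcoregions(dfNA, medianCols = "dz")
  expect_equal(sNA$medians$dz$median, 200)
  expect_equal(sNA$medians$dz$nExcluded, 1)
})
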