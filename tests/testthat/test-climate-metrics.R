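test_that("VPD from temperature and humidity follows the Magnus closed form", {
  expect_equal(vpdFromTRH(20, 20, 100, 100), 0)       # saturation
  es20 <- 0.6108 * exp(17.27 * 20 / (20 + 237.3))     # independent evaluation
  expect_equal(vpdFromTRH(20, 20, 50, 50), es20 / 2, tolerance = 1e-12)
  # dry limit: VPD equals the mean saturation pressure
  es30 <- 0.6108 * exp(17.27 * 30 / (30 + 237.3))
  es10 <- 0.6108 * exp(17.27 * 10 / (10 + 237.3))
  expect_equal(vpdFromTRH(30, 10, 0, 0), (es30 + es10) / 2, tolerance = 1e-12)
  expect_error(vpdFromTRH(20, 10, 120, 50), "\\[0, 100\\]")
  expect_error(vpdFromTRH(10, 20, 80, 40), "tmax")
})

test_that("VPD is monotone in temperature and humidity", {
  t <- seq(0, 40, by = 2)
  v <- vpdFromTRH(t + 5, t, rep(60, length(t)), rep(30, length(t)))
  expect_true(all(diff(v) > 0))
  rh <- seq(0, 100, by = 5)
  v2 <- vpdFromTRH(rep(25, length(rh)), rep(15, length(rh)), rh, rh)
  expect_true(all(diff(v2) < 0))
})

test_that("warm-season means cover exactly May through September", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  m <- warmSeasonMean(dates, rep(3.5, length(dates)))
  expect_equal(unname(m), c(3.5, 3.5))
  # day count: 153 days per warm season
  ws <- dates[format(dates, "%m") %in% c("05", "06", "07", "08", "09") &
              format(dates, "%Y") == "2001"]
  expect_equal(length(ws), 153)
  # order invariance and a direct-summation oracle on a sinusoid
  doy <- as.integer(format(dates, "%j"))
  vals <- 1.5 + sin(2 * pi * doy / 365)
  perm <- sample(seq_along(dates))
  m1 <- warmSeasonMean(dates, vals)
  m2 <- warmSeasonMean(dates[perm], vals[perm])
  expect_equal(m1, m2)
  keep <- format(dates, "%Y") == "2001" &
    format(dates, "%m") %in% c("05", "06", "07", "08", "09")
  expect_equal(unname(m1["2001"]), sum(vals[keep]) / 153, tolerance = 1e-12)
  # missing days are an error naming the gap
  drop <- dates != as.Date("2001-07-04")
  expect_error(warmSeasonMean(dates[drop], vals[drop]), "2001-07-04")
})

test_that("temporal trends equal the normal-equations slope", {
  years <- 1984:2017
  expect_equal(unname(temporalTrend(matrix(5 + 0.3 * (years - 1984),
                                           nrow = 1), years)), 0.3,
               tolerance = 1e-12)
  expect_equal(unname(temporalTrend(matrix(rep(2, 34), nrow = 1), years)), 0)
  set.seed(5)
  v <- 1 + 0.01 * years + rnorm(34, 0, 0.2)
  hand <- sum((years - mean(years)) * (v - mean(v))) /
    sum((years - mean(years))^2)
  expect_equal(unname(temporalTrend(matrix(v, nrow = 1), years)), hand,
               tolerance = 1e-12)
})

test_that("elevational gradients come out exactly on linear fields", {
  g <- uniformForestGrid(500, 3000, by = 50)
  vpd <- 2.5 - 3e-4 * elevations(g)
  expect_equal(elevationalGradient(vpd, g), -3e-4, tolerance = 1e-14)
  expect_equal(elevationalGradient(rep(1.7, length(vpd)), g), 0)
  # toy 10-cell hand OLS
  e10 <- seq(1000, 1900, by = 100)
  set.seed(3)
  v10 <- 2 - 2e-4 * e10 + rnorm(10, 0, 0.01)
  hand <- sum((e10 - mean(e10)) * (v10 - mean(v10))) / sum((e10 - mean(e10))^2)
  g10 <- ForestGrid(e10, rep(TRUE, 10))
  expect_equal(elevationalGradient(v10, g10, minCells = 10), hand,
               tolerance = 1e-12)
  expect_error(elevationalGradient(v10, g10), "30")
  gFlat <- ForestGrid(rep(1000, 40), rep(TRUE, 40))
  expect_error(elevationalGradient(rnorm(40), gFlat), "relief")
})

test_that("elevational velocity is the signed isoline speed", {
  v <- elevationalVelocity(0.00178, -2e-4, 34)
  expect_equal(v@velocity, 8.9, tolerance = 1e-12)
  expect_equal(v@totalDisplacement, 302.6, tolerance = 1e-9)
  expect_equal(elevationalVelocity(0, -2e-4, 34)@velocity, 0)
  # scale invariance: doubling trend and gradient leaves velocity unchanged
  expect_equal(elevationalVelocity(2 * 0.00178, -4e-4, 34)@velocity, 8.9,
               tolerance = 1e-12)
  # a VPD field increasing with elevation sends isolines downhill
  expect_equal(elevationalVelocity(0.001, 2e-4, 34)@velocity, -5)
  weak <- elevationalVelocity(0.001, 1e-6, 34)
  expect_true(weak@weakGradient)
  expect_true(is.na(weak@velocity))
})

test_that("velocity on a generated noise-free field equals trend / lapse", {
  g <- generateLandscape(landscapeConfig(seed = 21))
  cc <- climateConfig(lapse = 2e-4, trend = 0.00178, interannualSd = 0,
                      spatialNoiseSd = 0, seed = 21)
  v <- generateClimate(g, cc)
  years <- as.numeric(dimnames(v)[[3]])
  dvdt <- temporalTrend(v, years)
  dvde <- elevationalGradient(apply(v, c(1, 2), mean), g)
  vel <- elevationalVelocity(as.numeric(dvdt), dvde, length(years))
  expect_equal(vel@velocity, 8.9, tolerance = 1e-6)
  expect_equal(vel@totalDisplacement, 302.6, tolerance = 1e-4)
})

test_that("the temperature decomposition brackets pure-T and pure-RH cases", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2011-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y")) - 2000
  doy <- as.integer(format(dates, "%j"))
  season <- sin(2 * pi * doy / 365)
  # warming temperature, time-constant RH: fraction exactly 1
  tmin <- 8 + 5 * season + 0.1 * yr
  tmax <- tmin + 10
  d1 <- vpdTemperatureDecomposition(dates, tmax, tmin, rep(80, length(yr)),
                                    rep(40, length(yr)))
  expect_false(d1@undefined)
  expect_equal(d1@fractionTemperature, 1, tolerance = 1e-9)
  # constant temperature, drying RH: fraction exactly 0
  n <- length(yr)
  d0 <- vpdTemperatureDecomposition(dates, rep(22, n), rep(12, n),
                                    pmax(80 - 1.5 * yr, 0),
                                    pmax(40 - 1.5 * yr, 0))
  expect_equal(d0@fractionTemperature, 0, tolerance = 1e-9)
  # mixed trends: matches an independent rerun-with-frozen-RH computation
  rhmax <- pmax(80 - 1 * yr, 0)
  rhmin <- pmax(40 - 1 * yr, 0)
  dm <- vpdTemperatureDecomposition(dates, tmax, tmin, rhmax, rhmin,
                                    window = 0L)
  key <- format(dates, "%m-%d")
  clmax <- ave(rhmax, key)
  clmin <- ave(rhmin, key)
  frozen <- warmSeasonMean(dates, vpdFromTRH(tmax, tmin, clmax, clmin))
  obs <- warmSeasonMean(dates, vpdFromTRH(tmax, tmin, rhmax, rhmin))
  yy <- as.numeric(names(obs))
  slope <- function(v) unname(coef(lm(v ~ yy))[2])
  expect_equal(dm@fractionTemperature, slope(frozen) / slope(obs),
               tolerance = 1e-9)
  expect_lt(dm@fractionTemperature, 1)
  expect_gt(dm@fractionTemperature, 0)
})
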