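test_that("degenerate elevation range gives a flat DEM", {
  g <- generateLandscape(landscapeConfig(elevRange = c(1000, 1000),
                                         reliefRoughness = 0,
                                         forestBand = c(0, 4000),
                                         taperWidth = 0, seed = 3))
  expect_true(all(elevations(g) == 1000))
})

test_that("zero taper yields an exact elevation-band forest mask", {
  cfg <- landscapeConfig(elevRange = c(500, 3500), reliefRoughness = 0,
                         forestBand = c(1000, 2000), taperWidth = 0, seed = 5)
  g <- generateLandscape(cfg)
  e <- elevations(g)
  expect_identical(forestMask(g), e >= 1000 & e <= 2000)
})

test_that("landscapes are reproducible under a fixed seed", {
  cfg <- landscapeConfig(seed = 42)
  g1 <- generateLandscape(cfg)
  g2 <- generateLandscape(cfg)
  expect_identical(elevations(g1), elevations(g2))
  expect_identical(forestMask(g1), forestMask(g2))
  g3 <- generateLandscape(landscapeConfig(seed = 43))
  expect_false(identical(elevations(g1), elevations(g3)))
})

test_that("grids smaller than 8x8 are rejected", {
  expect_error(landscapeConfig(nx = 4, ny = 4), "8x8")
})

test_that("noise-free climate fields are exactly linear in elevation and time", {
  g <- generateLandscape(landscapeConfig(seed = 7))
  cc <- climateConfig(lapse = 2e-4, trend = 0.00178, interannualSd = 0,
                      spatialNoiseSd = 0, seed = 7)
  v <- generateClimate(g, cc)
  years <- as.numeric(dimnames(v)[[3]])
  # fitted per-cell trend recovers the input exactly
  tr <- temporalTrend(v, years)
  expect_equal(as.numeric(tr), rep(0.00178, length(tr)), tolerance = 1e-12)
  # fitted elevational gradient recovers -lapse exactly
  clim <- apply(v, c(1, 2), mean)
  expect_equal(elevationalGradient(clim, g), -2e-4, tolerance = 1e-12)
  # zero trend: every cell's series has OLS slope 0
  cc0 <- climateConfig(trend = 0, interannualSd = 0, spatialNoiseSd = 0)
  v0 <- generateClimate(g, cc0)
  expect_equal(max(abs(temporalTrend(v0, years))), 0, tolerance = 1e-14)
})

test_that("noisy per-cell OLS trends cover the generating trend", {
  # Monte-Carlo check against the stated generating model: with pure spatial
  # noise (sd 0.05), per-cell 34-year OLS trends should sit within 3
  # standard errors of the prescribed trend for nearly all cells and seeds.
  hits <- total <- 0
  for (s in 1:25) {
    g <- generateLandscape(landscapeConfig(nx = 10L, ny = 10L, seed = s,
                                           forestBand = c(0, 4000),
                                           taperWidth = 0))
    cc <- climateConfig(trend = 0.00178, interannualSd = 0,
                        spatialNoiseSd = 0.05, seed = 100 + s)
    v <- generateClimate(g, cc)
    years <- as.numeric(dimnames(v)[[3]])
    tr <- as.numeric(temporalTrend(v, years))
    # conservative per-cell slope se bound: sd(noise)/sqrt(sum((t-tbar)^2))
    se <- 0.05 / sqrt(sum((years - mean(years))^2))
    hits <- hits + sum(abs(tr - 0.00178) <= 3 * se)
    total <- total + length(tr)
  }
  expect_gte(hits / total, 0.95)
})

test_that("burn masks are contiguous subsets of the forest, reproducibly", {
  cfg <- runConfig(nEcoregions = 1)
  sim <- simulateEcoregion(cfg, 1)
  for (b in sim$burns)
    expect_true(all(forestMask(sim$grid)[burnMask(b)]))
  sim2 <- simulateEcoregion(cfg, 1)
  expect_identical(lapply(sim$burns, burnMask), lapply(sim2$burns, burnMask))
})

test_that("fire-size floor and zero ignitions empty the record", {
  g <- generateLandscape(landscapeConfig(seed = 11))
  cc <- climateConfig(seed = 11)
  v <- generateClimate(g, cc)
  big <- flammabilityConfig(minFireCells = length(elevations(g)) + 1L,
                            seed = 11)
  burns <- generateFires(g, v, big)
  expect_true(all(vapply(burns, function(b) sum(burnMask(b)) == 0,
                         logical(1))))
  none <- flammabilityConfig(ignitionsPerYear = 0, seed = 11)
  burns0 <- generateFires(g, v, none)
  expect_true(all(vapply(burns0, function(b) sum(burnMask(b)) == 0,
                         logical(1))))
})

test_that("beta = 0 removes the elevational forcing of Z90 trends", {
  # with flammability independent of VPD the mean estimated Z90 slope over
  # seeds should be indistinguishable from zero
  slopes <- vapply(1:40, function(s) {
    g <- generateLandscape(landscapeConfig(nx = 24L, ny = 24L, seed = s))
    cc <- climateConfig(seed = 1000 + s)
    v <- generateClimate(g, cc)
    fl <- flammabilityConfig(alpha = -0.5, beta = 0, ignitionsPerYear = 6,
                             seed = 2000 + s)
    burns <- generateFires(g, v, fl)
    dists <- lapply(burns, function(b) normalizedBurnDistribution(g, b))
    tryCatch(z90Trend(dists, nBoot = 20, seed = s)@slope,
             error = function(e) NA_real_)
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  ci <- mean(slopes) + c(-1, 1) * qt(0.995, length(slopes) - 1) *
    sd(slopes) / sqrt(length(slopes))
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("the oracle reduces to the flat normalized distribution when beta = 0", {
  g <- generateLandscape(landscapeConfig(seed = 9))
  cc <- climateConfig(interannualSd = 0, spatialNoiseSd = 0, seed = 9)
  v <- generateClimate(g, cc)
  fl <- flammabilityConfig(alpha = 0, beta = 0, seed = 9)
  truth <- trueZ90Oracle(g, v, fl, cc)
  # constant burn probability: the normalized distribution is flat over the
  # forest support, so the oracle Z90 equals the Z90 of an everything-burned
  # year, i.e. about min + 0.9 * span of the forest elevations
  allBurned <- AnnualBurn(1984L, forestMask(g))
  zFlat <- zQuantile(normalizedBurnDistribution(g, allBurned), 0.9)
  expect_equal(unname(trueZ90(truth)), rep(zFlat, 34), tolerance = 1e-9)
  e <- elevations(g)[forestMask(g)]
  expect_lt(abs(zFlat - (min(e) + 0.9 * (max(e) - min(e)))), 60)
})

test_that("oracle velocity is trend / lapse and the toy oracle matches hand numbers", {
  g <- generateLandscape(landscapeConfig(seed = 2))
  cc <- climateConfig(lapse = 2e-4, trend = 0.00178, seed = 2)
  v <- generateClimate(g, cc)
  truth <- trueZ90Oracle(g, v, flammabilityConfig(seed = 2), cc)
  expect_equal(trueVelocity(truth), 8.9, tolerance = 1e-12)

  # 3-cell toy with burn probabilities 0.1 / 0.1 / 0.8: hand-derived weighted
  # percentile of the normalized distribution is the top elevation
  toy <- ForestGrid(c(1000, 1500, 2000), rep(TRUE, 3))
  fl <- flammabilityConfig(alpha = 0, beta = 1, seed = 1)
  vpd <- array(log(c(0.1, 0.1, 0.8) / (1 - c(0.1, 0.1, 0.8))),
               dim = c(1, 3, 1), dimnames = list(NULL, NULL, 1984))
  tt <- trueZ90Oracle(toy, vpd, fl, climateConfig(seed = 1))
  expect_equal(unname(trueZ90(tt)), 2000)
})
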