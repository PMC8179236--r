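# Synthetic landscape / climate / fire generator.
#
# The generator stands in for the gridded burn, forest-cover, DEM and daily
# meteorology products a real-data analysis would ingest. Everything is
# seeded: the same config always yields bit-identical output.

#' Generate a synthetic forest landscape
#'
#' Builds a DEM as a linear west-east elevation ramp plus a smoothed Gaussian
#' relief field scaled by \code{reliefRoughness}, clipped to
#' \code{elevRange}, and a forest mask that is certain inside the forest
#' elevation band and tapers linearly to zero over \code{taperWidth} metres
#' outside it.
#'
#' @param cfg a \linkS4class{LandscapeConfig}.
#' @param ecoregion ecoregion label for the resulting grid.
#' @return A \linkS4class{ForestGrid}.
#' @examples
#' g <- generateLandscape(landscapeConfig(seed = 7))
#' g
#' @export
generateLandscape <- function(cfg, ecoregion = "ECO1") {
  stopifnot(is(cfg, "LandscapeConfig"))
  validObject(cfg)
  nr <- cfg@ny
  nc <- cfg@nx
  lo <- cfg@elevRange[1]
  hi <- cfg@elevRange[2]
  withSeed(cfg@seed, {
    ramp <- matrix(rep(seq(lo, hi, length.out = nc), each = nr), nr, nc)
    if (cfg@reliefRoughness > 0 && hi > lo) {
      relief <- smoothField(nr, nc) * cfg@reliefRoughness * (hi - lo) / 4
      dem <- pmin(pmax(ramp + relief, lo), hi)
    } else {
      dem <- ramp
    }
    p <- forestProbability(dem, cfg@forestBand, cfg@taperWidth)
    forest <- matrix(runif(nr * nc) < p, nr, nc)
    if (!any(forest))
      stop("landscape config produced no forest cells")
    ForestGrid(dem, forest, cellArea = cfg@cellSize^2, ecoregion = ecoregion)
  })
}

# Forest membership probability: 1 inside the band, linear taper outside.
forestProbability <- function(elev, band, taper) {
  d <- pmax(band[1] - elev, elev - band[2], 0)
  if (taper > 0) pmax(1 - d / taper, 0) else as.numeric(d == 0)
}

#' Generate synthetic warm-season VPD fields
#'
#' VPD(cell, year) = vpdBase - lapse * E(cell) + trend * (year - start)
#' plus a shared interannual Gaussian deviation per year and a smoothed
#' spatial Gaussian field per year, clipped at zero. Fields are generated
#' directly at warm-season-mean resolution.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param cfg a \linkS4class{ClimateConfig}.
#' @return A 3-d array (rows, cols, years) of warm-season mean VPD in kPa,
#'   with years as dimnames on the third axis.
#' @export
generateClimate <- function(grid, cfg) {
  stopifnot(is(grid, "ForestGrid"), is(cfg, "ClimateConfig"))
  validObject(cfg)
  years <- seq(cfg@years[1], cfg@years[2])
  ny <- length(years)
  e <- elevations(grid)
  nr <- nrow(e)
  nc <- ncol(e)
  withSeed(cfg@seed, {
    eps_t <- if (cfg@interannualSd > 0) rnorm(ny, 0, cfg@interannualSd)
             else numeric(ny)
    out <- array(0, dim = c(nr, nc, ny), dimnames = list(NULL, NULL, years))
    for (i in seq_len(ny)) {
      field <- cfg@vpdBase - cfg@lapse * e +
        cfg@trend * (years[i] - years[1]) + eps_t[i]
      if (cfg@spatialNoiseSd > 0)
        field <- field + smoothField(nr, nc) * cfg@spatialNoiseSd
      out[, , i] <- pmax(field, 0)
    }
    out
  })
}

#' Simulate annual fires by region growing
#'
#' Per year, the number of ignitions is Poisson with mean
#' \code{ignitionsPerYear}; ignition cells are drawn without replacement
#' among forest cells with probability proportional to the logistic
#' flammability plogis(alpha + beta * VPD); each fire grows by breadth-first
#' region growing in which an offered forest neighbour joins with that same
#' per-cell probability; fires smaller than \code{minFireCells} cells are
#' discarded. Burn masks are therefore contiguous patches and always subsets
#' of the forest mask.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param vpd array from \code{\link{generateClimate}}, aligned to the grid.
#' @param cfg a \linkS4class{FlammabilityConfig}.
#' @return A list of \linkS4class{AnnualBurn}, one per year.
#' @export
generateFires <- function(grid, vpd, cfg) {
  stopifnot(is(grid, "ForestGrid"), is(cfg, "FlammabilityConfig"))
  validObject(cfg)
  e <- elevations(grid)
  if (!all(dim(vpd)[1:2] == dim(e)))
    stop("vpd array is not aligned to the grid")
  years <- as.integer(dimnames(vpd)[[3]])
  forest <- forestMask(grid)
  withSeed(cfg@seed, {
    lapply(seq_along(years), function(i) {
      pjoin <- logistic(cfg@alpha + cfg@beta * vpd[, , i])
      nIgn <- rpois(1, cfg@ignitionsPerYear)
      burn <- cpp_simulate_year(nrow(e), ncol(e), as.logical(forest),
                                as.numeric(pjoin), nIgn, cfg@minFireCells)
      AnnualBurn(years[i], matrix(burn, nrow(e), ncol(e)),
                 severityFiltered = TRUE)
    })
  })
}

#' Ground-truth oracle for the expected normalized burn elevation
#'
#' Computes, per year, the expected normalized elevational burn distribution
#' by direct per-cell evaluation (no perimeter sampling): each forest cell is
#' weighted by its area times its logistic burn probability divided by the
#' forest elevation density at its elevation, and the weighted 90th
#' percentile is taken. Also returns the closed-form elevational climate
#' velocity trend / lapse.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param vpd array from \code{\link{generateClimate}}.
#' @param flammability a \linkS4class{FlammabilityConfig}.
#' @param climate the \linkS4class{ClimateConfig} used (for trend / lapse).
#' @param binWidth elevation bin width (m) for the forest density.
#' @param q quantile level (default 0.9).
#' @return A \linkS4class{SyntheticTruth}.
#' @export
trueZ90Oracle <- function(grid, vpd, flammability, climate, binWidth = 50,
                          q = 0.9) {
  stopifnot(is(grid, "ForestGrid"), is(flammability, "FlammabilityConfig"),
            is(climate, "ClimateConfig"))
  years <- as.integer(dimnames(vpd)[[3]])
  forest <- forestMask(grid)
  e <- elevations(grid)[forest]
  area <- cellAreas(grid)[forest]
  dens <- forestElevationDensity(grid, binWidth = binWidth)
  pE <- elevDensityAt(dens, e)
  z90 <- rep(NA_real_, length(years))
  excluded <- integer()
  for (i in seq_along(years)) {
    p <- logistic(flammability@alpha +
                  flammability@beta * vpd[, , i][forest])
    w <- area * p / pE
    if (sum(w) <= 0) {
      excluded <- c(excluded, years[i])
      next
    }
    z90[i] <- weightedQuantile(e, w, q)
  }
  keep <- !is.na(z90)
  new("SyntheticTruth",
      trueVelocity = climate@trend / climate@lapse,
      trueZ90 = setNames(z90[keep], years[keep]),
      excludedYears = excluded,
      configs = list(flammability = flammability, climate = climate))
}
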