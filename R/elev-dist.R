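# Normalized elevational distribution of burned forest: the Bayes-normalised
# burn density p(E|B)/p(E), the Z90 statistic and burned-area summaries.

#' Forest elevation density P(E)
#'
#' Area-weighted histogram density of forest elevation over fixed-width bins
#' (default 50 m), normalised to integrate to one, together with the
#' empirical CDF and its quantile inverse.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param binWidth bin width in metres.
#' @return An \linkS4class{ElevDensity}.
#' @examples
#' g <- ForestGrid(seq(1000, 2000, by = 10), rep(TRUE, 101))
#' d <- forestElevationDensity(g)
#' elevQuantile(d, 0.9)
#' @export
forestElevationDensity <- function(grid, binWidth = 50) {
  stopifnot(is(grid, "ForestGrid"), binWidth > 0)
  forest <- forestMask(grid)
  e <- elevations(grid)[forest]
  area <- cellAreas(grid)[forest]
  total <- sum(area)
  if (total <= 0) stop("zero forest area")
  if (max(e) == min(e)) {
    # point mass: a single bin centred on the common elevation
    breaks <- c(e[1] - binWidth / 2, e[1] + binWidth / 2)
    return(new("ElevDensity", breaks = breaks,
               density = 1 / binWidth, area = total, totalArea = total,
               pointMass = TRUE))
  }
  b0 <- floor(min(e) / binWidth) * binWidth
  b1 <- ceiling(max(e) / binWidth) * binWidth
  if (b1 == b0) b1 <- b0 + binWidth  # range smaller than one bin
  breaks <- seq(b0, b1, by = binWidth)  # last bin closed above
  idx <- binIndex(e, breaks)
  binArea <- vapply(seq_len(length(breaks) - 1L),
                    function(i) sum(area[idx == i]), numeric(1))
  new("ElevDensity", breaks = breaks,
      density = binArea / (total * binWidth), area = binArea,
      totalArea = total, pointMass = FALSE)
}

# Half-open bin assignment [b_i, b_{i+1}); the last bin is closed above.
binIndex <- function(e, breaks) {
  idx <- findInterval(e, breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(breaks) - 1L)
}

#' Evaluate a forest elevation density
#'
#' @param dens an \linkS4class{ElevDensity}.
#' @param e elevations (m).
#' @param interpolate if \code{TRUE}, interpolate linearly between bin
#'   centres (a smoother curve for plotting); the default piecewise-constant
#'   evaluation reproduces the binned area ratio exactly when used as the
#'   normalisation weight.
#' @return density per metre at \code{e}.
#' @export
elevDensityAt <- function(dens, e, interpolate = FALSE) {
  stopifnot(is(dens, "ElevDensity"))
  if (dens@pointMass) return(rep(dens@density, length(e)))
  if (interpolate) {
    mids <- (dens@breaks[-1] + dens@breaks[-length(dens@breaks)]) / 2
    return(stats::approx(mids, dens@density, xout = e, rule = 2)$y)
  }
  dens@density[binIndex(e, dens@breaks)]
}

#' Quantile of the forest elevation distribution
#'
#' Inverse of the histogram CDF: the smallest elevation whose cumulative
#' area fraction reaches q, interpolated linearly within the attaining bin.
#' Empty bins (gaps in the elevation support) are never interpolated across.
#'
#' @param dens an \linkS4class{ElevDensity}.
#' @param q quantile levels in (0, 1).
#' @return elevations (m).
#' @export
elevQuantile <- function(dens, q) {
  stopifnot(is(dens, "ElevDensity"), all(q > 0 & q < 1))
  if (dens@pointMass) return(rep(mean(dens@breaks), length(q)))
  binnedCdfQuantile(dens@breaks, cumsum(dens@area) / dens@totalArea, q)
}

# Inverse of a binned CDF (cdf = cumulative mass at the upper edge of each
# bin): smallest position attaining q, linear within the attaining bin.
binnedCdfQuantile <- function(breaks, cdf, q) {
  lo <- c(0, cdf[-length(cdf)])
  vapply(q, function(p) {
    j <- which(cdf >= p - 1e-12 & cdf > lo)[1]
    if (is.na(j)) return(breaks[length(breaks)])
    frac <- (p - lo[j]) / (cdf[j] - lo[j])
    breaks[j] + max(min(frac, 1), 0) * (breaks[j + 1] - breaks[j])
  }, numeric(1))
}

#' Normalized elevational distribution of burned forest
#'
#' Each burned forest cell contributes its area divided by the forest
#' elevation density at its elevation; the weighted sample renormalises to
#' the Bayes ratio p(E|B)/p(E). The binned density equals burned area per
#' bin over forest area per bin, renormalised to integrate to one.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param burn an \linkS4class{AnnualBurn} aligned to the grid (severity
#'   filter already applied). Burned cells outside the forest mask are
#'   ignored, as only burned forest enters the analysis.
#' @param binWidth elevation bin width (m).
#' @param density optionally a precomputed \linkS4class{ElevDensity} for the
#'   grid (must use the same bin width).
#' @return A \linkS4class{NormalizedElevDist}; fire-free years give an
#'   explicitly flagged empty distribution.
#' @export
normalizedBurnDistribution <- function(grid, burn, binWidth = 50,
                                       density = NULL) {
  stopifnot(is(grid, "ForestGrid"), is(burn, "AnnualBurn"))
  if (!all(dim(burnMask(burn)) == dim(elevations(grid))))
    stop("burn mask is not aligned to the grid")
  if (is.null(density)) density <- forestElevationDensity(grid, binWidth)
  forest <- forestMask(grid)
  burned <- burnMask(burn) & forest
  if (!any(burned)) {
    return(new("NormalizedElevDist", elev = numeric(), weight = numeric(),
               breaks = density@breaks,
               density = rep(0, length(density@breaks) - 1L),
               nBurnedCells = 0L, totalBurnedArea = 0, empty = TRUE,
               year = burnYear(burn), ecoregion = ecoregionId(grid)))
  }
  e <- elevations(grid)[burned]
  area <- cellAreas(grid)[burned]
  pE <- elevDensityAt(density, e)
  if (any(pE <= 0))
    stop("burned cell in an elevation bin with zero forest area")
  w <- area / pE
  # binned ratio: burned area per bin / forest area per bin, renormalised
  idx <- binIndex(e, density@breaks)
  nb <- length(density@breaks) - 1L
  burnedBin <- vapply(seq_len(nb), function(i) sum(area[idx == i]),
                      numeric(1))
  ratio <- ifelse(density@area > 0, burnedBin / density@area, 0)
  bw <- diff(density@breaks)
  dens <- ratio / sum(ratio * bw)
  new("NormalizedElevDist", elev = e, weight = w, breaks = density@breaks,
      density = dens, nBurnedCells = sum(burned),
      totalBurnedArea = sum(area), empty = FALSE,
      year = burnYear(burn), ecoregion = ecoregionId(grid))
}

#' Quantile of the normalized burn distribution (Z90 for q = 0.9)
#'
#' Weighted quantile of the normalised elevation sample, using the frozen
#' replication-consistent type-7 convention of
#' \code{\link{weightedQuantile}}.
#'
#' @param dist a \linkS4class{NormalizedElevDist}.
#' @param q quantile level in (0, 1).
#' @return elevation in metres.
#' @export
zQuantile <- function(dist, q = 0.9) {
  stopifnot(is(dist, "NormalizedElevDist"), q > 0, q < 1)
  if (dist@empty)
    stop("empty burn distribution: years without large forest fires are ",
         "excluded from the analysis; skip this year")
  weightedQuantile(dist@elev, dist@weight, q)
}

#' Burned forest area above an elevation threshold
#'
#' BA90 is the special case where the threshold is the 90th percentile of
#' the forest elevation distribution.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param burn an \linkS4class{AnnualBurn}.
#' @param threshold elevation threshold in metres, or \code{NULL} to use
#'   \code{quantile}.
#' @param quantile forest-elevation quantile in (0, 1) resolving the
#'   threshold via \code{\link{forestElevationDensity}}.
#' @param binWidth bin width for the quantile form.
#' @return burned forest area in km^2 strictly above the threshold.
#' @export
burnedAreaAbove <- function(grid, burn, threshold = NULL, quantile = NULL,
                            binWidth = 50) {
  stopifnot(is(grid, "ForestGrid"), is(burn, "AnnualBurn"))
  if (is.null(threshold)) {
    stopifnot(!is.null(quantile))
    threshold <- elevQuantile(forestElevationDensity(grid, binWidth),
                              quantile)
  }
  burned <- burnMask(burn) & forestMask(grid)
  sum(cellAreas(grid)[burned & elevations(grid) > threshold])
}

#' Burned forest area by elevation band
#'
#' Bands are contiguous half-open intervals [low, high) defined by a
#' strictly increasing edge vector (use -Inf / Inf for open ends), so they
#' partition the elevation axis without double counting.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param burn an \linkS4class{AnnualBurn}.
#' @param edges strictly increasing band edges (m).
#' @return named numeric vector of burned forest area (km^2) per band.
#' @export
bandBurnedArea <- function(grid, burn, edges = c(-Inf, 1000, 1500, 2000,
                                                 2500, 3000, Inf)) {
  stopifnot(is(grid, "ForestGrid"), is(burn, "AnnualBurn"))
  if (any(diff(edges) <= 0))
    stop("band edges must be strictly increasing (overlapping bands rejected)")
  burned <- burnMask(burn) & forestMask(grid)
  e <- elevations(grid)[burned]
  area <- cellAreas(grid)[burned]
  nb <- length(edges) - 1L
  idx <- findInterval(e, edges)  # [low, high)
  out <- vapply(seq_len(nb), function(i) sum(area[idx == i]), numeric(1))
  lab <- function(lo, hi) {
    if (is.infinite(lo)) paste0("band_lt_", hi)
    else if (is.infinite(hi)) paste0("band_gt_", lo)
    else paste0("band_", lo, "_", hi)
  }
  names(out) <- mapply(lab, edges[-length(edges)], edges[-1])
  out
}

#' Per-year fire elevation metrics for one ecoregion
#'
#' Builds the ecoregion-year metrics table: Z90, BA90 (burned area above the
#' forest-elevation 90th percentile), burned area above fixed thresholds,
#' burned area per elevation band, total burned forest area, and a
#' fire-year flag.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param burns list of \linkS4class{AnnualBurn}.
#' @param binWidth elevation bin width (m).
#' @param thresholds fixed elevation thresholds (m).
#' @param bands band edges (m).
#' @return A \linkS4class{FireMetricsSeries}.
#' @export
fireMetricsSeries <- function(grid, burns, binWidth = 50,
                              thresholds = c(2000, 2500, 3000),
                              bands = c(-Inf, 1000, 1500, 2000, 2500, 3000,
                                        Inf)) {
  stopifnot(is(grid, "ForestGrid"), length(burns) > 0)
  dens <- forestElevationDensity(grid, binWidth)
  q90 <- if (dens@pointMass) mean(dens@breaks) else elevQuantile(dens, 0.9)
  rows <- lapply(burns, function(b) {
    dist <- normalizedBurnDistribution(grid, b, binWidth, density = dens)
    hasFire <- !isEmpty(dist)
    bandArea <- bandBurnedArea(grid, b, bands)
    thr <- vapply(thresholds, function(th) burnedAreaAbove(grid, b, th),
                  numeric(1))
    names(thr) <- paste0("ba_above_", thresholds)
    df <- data.frame(ecoregion = ecoregionId(grid), year = burnYear(b),
                     z90 = if (hasFire) zQuantile(dist, 0.9) else NA_real_,
                     ba90 = burnedAreaAbove(grid, b, q90),
                     total_burned_km2 = dist@totalBurnedArea,
                     has_fire = hasFire, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(as.list(thr)), as.data.frame(as.list(bandArea)))
  })
  new("FireMetricsSeries", table = do.call(rbind, rows))
}
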