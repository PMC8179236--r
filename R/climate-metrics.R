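# Warm-season VPD aggregation, VPD from temperature and relative humidity,
# elevational climate velocity, and the temperature decomposition of VPD
# trends.

#' Daily vapor pressure deficit from temperature and relative humidity
#'
#' Magnus/FAO-56 formulation: saturation vapour pressure
#' es(T) = 0.6108 exp(17.27 T / (T + 237.3)) kPa; mean saturation pressure is
#' the average of es at the daily extremes; actual vapour pressure pairs the
#' daily maximum RH with the minimum temperature and vice versa:
#' ea = (es(tmin) rhmax + es(tmax) rhmin) / 200. VPD = max(es_mean - ea, 0).
#'
#' @param tmax,tmin daily maximum/minimum air temperature, degrees C.
#' @param rhmax,rhmin daily maximum/minimum relative humidity, percent.
#' @return daily VPD in kPa (vectorised).
#' @examples
#' vpdFromTRH(30, 12, 80, 25)
#' @export
vpdFromTRH <- function(tmax, tmin, rhmax, rhmin) {
  if (any(rhmax < 0 | rhmax > 100 | rhmin < 0 | rhmin > 100))
    stop("relative humidity must lie in [0, 100]")
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  esMean <- (satVapourPressure(tmax) + satVapourPressure(tmin)) / 2
  ea <- (satVapourPressure(tmin) * rhmax + satVapourPressure(tmax) * rhmin) /
    200
  pmax(esMean - ea, 0)
}

satVapourPressure <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Warm-season (May-September) mean of a daily series
#'
#' Arithmetic mean over May 1 through September 30 (153 days) per year.
#' Incomplete warm-season coverage is an error listing the gaps; records are
#' order-invariant.
#'
#' @param dates Date vector.
#' @param values matching daily values.
#' @return named numeric vector, one value per year.
#' @export
warmSeasonMean <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  dates <- as.Date(dates)
  mo <- as.integer(format(dates, "%m"))
  keep <- mo >= 5L & mo <= 9L
  dates <- dates[keep]
  values <- values[keep]
  if (anyDuplicated(dates)) stop("duplicated dates in the daily record")
  yr <- as.integer(format(dates, "%Y"))
  out <- vapply(sort(unique(yr)), function(y) {
    want <- seq(as.Date(sprintf("%d-05-01", y)),
                as.Date(sprintf("%d-09-30", y)), by = "day")
    have <- dates[yr == y]
    missing <- setdiff(as.character(want), as.character(have))
    if (length(missing))
      stop("incomplete warm season in ", y, ": missing ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)",
                                            length(missing) - 5) else "")
    mean(values[yr == y])
  }, numeric(1))
  names(out) <- sort(unique(yr))
  out
}

#' Per-cell temporal trend dVPD/dt
#'
#' OLS slope of the annual warm-season value on year, per cell.
#'
#' @param values numeric vector (one cell), matrix (cells x years) or 3-d
#'   array (rows x cols x years) of annual values.
#' @param years matching years; defaults to the last-dimension index.
#' @param minYears minimum record length (default 10).
#' @return slope(s) in value units per year, with the spatial shape of the
#'   input.
#' @export
temporalTrend <- function(values, years = NULL, minYears = 10L) {
  if (is.array(values) && length(dim(values)) == 3L) {
    d <- dim(values)
    if (is.null(years) && !is.null(dimnames(values)[[3]]))
      years <- as.numeric(dimnames(values)[[3]])
    m <- matrix(values, d[1] * d[2], d[3])
    return(matrix(temporalTrend(m, years, minYears), d[1], d[2]))
  }
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  ny <- ncol(values)
  if (is.null(years)) years <- seq_len(ny)
  stopifnot(length(years) == ny)
  if (ny < minYears) stop("at least ", minYears, " years are required")
  tc <- years - mean(years)
  drop(values %*% tc) / sum(tc^2)
}

#' Ecoregion elevational gradient dVPD/dE
#'
#' OLS slope of the cell climatological (long-term mean warm-season) value on
#' cell elevation across the ecoregion's cells.
#'
#' @param climatology per-cell climatological values (matrix matching the
#'   grid, or vector).
#' @param grid a \linkS4class{ForestGrid}.
#' @param cells "all" (default) or "forest".
#' @param minCells minimum number of cells.
#' @param minRelief minimum elevation span in metres for the gradient to be
#'   identifiable.
#' @return slope in kPa per metre.
#' @export
elevationalGradient <- function(climatology, grid, cells = c("all", "forest"),
                                minCells = 30L, minRelief = 100) {
  cells <- match.arg(cells)
  stopifnot(is(grid, "ForestGrid"))
  e <- as.numeric(elevations(grid))
  v <- as.numeric(climatology)
  stopifnot(length(e) == length(v))
  if (cells == "forest") {
    keep <- as.logical(forestMask(grid))
    e <- e[keep]
    v <- v[keep]
  }
  if (length(e) < minCells)
    stop("fewer than ", minCells, " cells: gradient unidentifiable")
  if (diff(range(e)) < minRelief)
    stop("relief below ", minRelief, " m: gradient unidentifiable")
  ec <- e - mean(e)
  sum(ec * v) / sum(ec^2)
}

#' Elevational climate velocity
#'
#' velocity = -dVPD/dt / dVPD/dE, i.e. the vertical speed of a VPD isoline,
#' signed upslope-positive: rising VPD over a gradient where VPD decreases
#' with elevation gives a positive (uphill) velocity. Cells (or ecoregions)
#' whose gradient magnitude falls below \code{minGradient} are flagged and
#' reported as undefined rather than silently dropped.
#'
#' @param dvpdDt temporal trend(s), kPa per year (scalar or per-cell vector).
#' @param dvpdDe elevational gradient, kPa per metre (scalar, per ecoregion).
#' @param recordYears record length in years (the multiplier for total
#'   displacement).
#' @param summary how to summarise per-cell velocities: "median" (default)
#'   or "mean".
#' @param minGradient gradient magnitude below which the velocity is
#'   undefined.
#' @return A \linkS4class{VelocityResult}.
#' @examples
#' elevationalVelocity(0.00178, -2e-4, 34)
#' @export
elevationalVelocity <- function(dvpdDt, dvpdDe, recordYears,
                                summary = c("median", "mean"),
                                minGradient = 1e-5) {
  summary <- match.arg(summary)
  stopifnot(length(dvpdDe) == 1L)
  if (!is.finite(dvpdDe) || abs(dvpdDe) < minGradient) {
    return(new("VelocityResult", dvpdDt = as.numeric(dvpdDt),
               dvpdDe = dvpdDe, velocity = NA_real_,
               velocityCells = rep(NA_real_, length(dvpdDt)),
               totalDisplacement = NA_real_, recordYears = recordYears,
               weakGradient = TRUE))
  }
  vc <- -as.numeric(dvpdDt) / dvpdDe
  v <- if (summary == "median") median(vc) else mean(vc)
  new("VelocityResult", dvpdDt = as.numeric(dvpdDt), dvpdDe = dvpdDe,
      velocity = v, velocityCells = vc,
      totalDisplacement = v * recordYears, recordYears = recordYears,
      weakGradient = FALSE)
}

#' Temperature decomposition of a VPD trend
#'
#' Recomputes daily VPD with relative humidity frozen at its day-of-year
#' climatology (mean over years, smoothed with a +/- \code{window}-day
#' running mean) while temperature varies as observed. The fraction of the
#' observed warm-season VPD trend attributable to temperature is the ratio
#' of the frozen-RH trend to the observed trend.
#'
#' @param dates Date vector of the full daily record.
#' @param tmax,tmin,rhmax,rhmin matching daily series.
#' @param window half-width (days) of the climatology smoothing window.
#' @param minTrend observed-trend magnitude (kPa/y) below which the fraction
#'   is undefined.
#' @return A \linkS4class{DecompositionResult}.
#' @export
vpdTemperatureDecomposition <- function(dates, tmax, tmin, rhmax, rhmin,
                                        window = 7L, minTrend = 1e-10) {
  dates <- as.Date(dates)
  n <- length(dates)
  stopifnot(length(tmax) == n, length(tmin) == n, length(rhmax) == n,
            length(rhmin) == n)
  obsDaily <- vpdFromTRH(tmax, tmin, rhmax, rhmin)
  obsAnnual <- warmSeasonMean(dates, obsDaily)
  years <- as.numeric(names(obsAnnual))
  obsTrend <- unname(temporalTrend(matrix(obsAnnual, nrow = 1), years))

  clmax <- doyClimatology(dates, rhmax, window)
  clmin <- doyClimatology(dates, rhmin, window)
  frozenDaily <- vpdFromTRH(tmax, tmin, pmin(pmax(clmax, 0), 100),
                            pmin(pmax(clmin, 0), 100))
  frozenAnnual <- warmSeasonMean(dates, frozenDaily)
  tTrend <- unname(temporalTrend(matrix(frozenAnnual, nrow = 1), years))

  undef <- abs(obsTrend) < minTrend
  new("DecompositionResult", observedTrend = obsTrend,
      temperatureOnlyTrend = tTrend,
      fractionTemperature = if (undef) NA_real_ else tTrend / obsTrend,
      undefined = undef)
}

# Day-of-year (month-day keyed, leap-safe) climatology with a +/- window-day
# running mean; returns one value per input date.
doyClimatology <- function(dates, values, window) {
  key <- format(dates, "%m-%d")
  clim <- tapply(values, key, mean)
  keys <- sort(names(clim))
  cl <- as.numeric(clim[keys])
  if (window > 0) {
    nk <- length(cl)
    sm <- vapply(seq_len(nk), function(i) {
      lo <- max(1L, i - window)
      hi <- min(nk, i + window)
      mean(cl[lo:hi])
    }, numeric(1))
    cl <- sm
  }
  cl[match(key, keys)]
}
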