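#' @import methods
#' @importFrom stats acf coef cor cor.test lm median pnorm qnorm quantile
#'   rbinom rnorm rpois runif sd setNames ks.test aggregate complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @useDynLib fireElev, .registration = TRUE
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

# ---------------------------------------------------------------------------
# Spatial substrate
# ---------------------------------------------------------------------------

#' ForestGrid: aligned DEM, forest mask and cell areas for one ecoregion
#'
#' The spatial substrate of every computation: a matrix of cell elevations
#' (m), a logical forest/woodland mask, per-cell areas (km^2) and an
#' ecoregion label.
#'
#' @slot elevation numeric matrix of cell elevations in metres.
#' @slot forest logical matrix, \code{TRUE} for forest/woodland cells.
#' @slot cellArea numeric matrix of cell areas in km^2.
#' @slot ecoregion single character label.
#' @export
setClass("ForestGrid",
  representation(elevation = "matrix", forest = "matrix",
                 cellArea = "matrix", ecoregion = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@elevation)
    if (!all(dim(object@forest) == d) || !all(dim(object@cellArea) == d))
      msg <- c(msg, "elevation, forest and cellArea must share dimensions")
    if (!all(is.finite(object@elevation)))
      msg <- c(msg, "elevations must be finite")
    if (!is.logical(object@forest))
      msg <- c(msg, "forest mask must be logical")
    if (any(object@cellArea <= 0))
      msg <- c(msg, "cell areas must be positive")
    if (!any(object@forest))
      msg <- c(msg, "grid must contain at least one forest cell")
    if (length(object@ecoregion) != 1L)
      msg <- c(msg, "ecoregion must be a single label")
    if (length(msg)) msg else TRUE
  })

#' Construct a ForestGrid
#'
#' @param elevation numeric matrix (or vector, treated as a 1-row grid) of
#'   elevations in metres.
#' @param forest logical matrix/vector marking forest cells.
#' @param cellArea cell area(s) in km^2; a scalar is recycled.
#' @param ecoregion ecoregion label.
#' @return A \linkS4class{ForestGrid}.
#' @examples
#' g <- ForestGrid(c(1000, 1500, 2000), c(TRUE, TRUE, TRUE))
#' forestArea(g)
#' @export
ForestGrid <- function(elevation, forest, cellArea = 1, ecoregion = "ECO") {
  if (!is.matrix(elevation)) elevation <- matrix(elevation, nrow = 1)
  if (!is.matrix(forest)) forest <- matrix(as.logical(forest), nrow = 1)
  if (!is.matrix(cellArea))
    cellArea <- matrix(rep_len(as.numeric(cellArea), length(elevation)),
                       nrow = nrow(elevation))
  new("ForestGrid", elevation = elevation, forest = forest,
      cellArea = cellArea, ecoregion = as.character(ecoregion))
}

#' AnnualBurn: binary burn mask for one year
#'
#' @slot year calendar year.
#' @slot burn logical matrix of burned cells (post severity filtering).
#' @slot severityFiltered whether the "unburned to low-severity" filter has
#'   been applied (a no-op flag for synthetic burns).
#' @export
setClass("AnnualBurn",
  representation(year = "integer", burn = "matrix",
                 severityFiltered = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@year) != 1L || is.na(object@year))
      msg <- c(msg, "year must be a single integer")
    if (!is.logical(object@burn))
      msg <- c(msg, "burn mask must be logical")
    if (length(msg)) msg else TRUE
  })

#' Construct an AnnualBurn
#' @param year calendar year.
#' @param burn logical matrix/vector of burned cells.
#' @param severityFiltered logical flag; \code{TRUE} when low-severity cells
#'   have already been removed.
#' @return An \linkS4class{AnnualBurn}.
#' @export
AnnualBurn <- function(year, burn, severityFiltered = TRUE) {
  if (!is.matrix(burn)) burn <- matrix(as.logical(burn), nrow = 1)
  new("AnnualBurn", year = as.integer(year), burn = burn,
      severityFiltered = as.logical(severityFiltered))
}

# ---------------------------------------------------------------------------
# Elevational distributions
# ---------------------------------------------------------------------------

#' ElevDensity: area-weighted histogram density of forest elevation
#'
#' The empirical probability function of forest elevation P(E): an
#' area-weighted histogram over fixed-width elevation bins, normalised to
#' integrate to one, with its CDF and quantile inverse.
#'
#' @slot breaks bin edges (m).
#' @slot density density per metre in each bin (integrates to 1).
#' @slot area forest area per bin (km^2).
#' @slot totalArea total forest area (km^2).
#' @slot pointMass TRUE when all forest lies at a single elevation.
#' @export
setClass("ElevDensity",
  representation(breaks = "numeric", density = "numeric", area = "numeric",
                 totalArea = "numeric", pointMass = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@breaks) != length(object@density) + 1L)
      msg <- c(msg, "breaks must have one more element than density")
    if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
    if (object@totalArea <= 0) msg <- c(msg, "total forest area must be > 0")
    if (length(msg)) msg else TRUE
  })

#' NormalizedElevDist: normalized elevational distribution of burned forest
#'
#' The Bayes-normalised burn distribution p(E|B)/p(E) for one ecoregion-year,
#' held both as a weighted elevation sample (each burned cell weighted by
#' cell area over the forest elevation density at its elevation) and as a
#' binned density (burned area per bin / forest area per bin, renormalised).
#'
#' @slot elev elevations of burned forest cells (m).
#' @slot weight positive weights (cell area / forest elevation density).
#' @slot breaks elevation bin edges (m).
#' @slot density normalised density per bin (integrates to 1).
#' @slot nBurnedCells number of burned forest cells.
#' @slot totalBurnedArea burned forest area (km^2).
#' @slot empty TRUE when the year had no burned forest cells.
#' @slot year calendar year.
#' @slot ecoregion ecoregion label.
#' @export
setClass("NormalizedElevDist",
  representation(elev = "numeric", weight = "numeric", breaks = "numeric",
                 density = "numeric", nBurnedCells = "integer",
                 totalBurnedArea = "numeric", empty = "logical",
                 year = "integer", ecoregion = "character"),
  validity = function(object) {
    msg <- character()
    if (object@empty) {
      if (length(object@elev) != 0L)
        msg <- c(msg, "empty distribution must carry no sample")
    } else {
      if (length(object@elev) != length(object@weight))
        msg <- c(msg, "sample and weights must match")
      if (any(!is.finite(object@weight)) || any(object@weight <= 0))
        msg <- c(msg, "weights must be positive and finite")
      if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
      wsum <- sum(object@density * diff(object@breaks))
      if (abs(wsum - 1) > 1e-9)
        msg <- c(msg, "density must integrate to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' FireMetricsSeries: per ecoregion-year fire elevation metrics
#'
#' One row per ecoregion-year with Z90, BA90, burned area above fixed
#' elevation thresholds, burned area per elevation band, total burned forest
#' area and a fire-year flag.
#'
#' @slot table data.frame of metrics.
#' @export
setClass("FireMetricsSeries",
  representation(table = "data.frame"),
  validity = function(object) {
    need <- c("ecoregion", "year", "z90", "ba90", "total_burned_km2",
              "has_fire")
    miss <- setdiff(need, names(object@table))
    if (length(miss))
      paste("missing columns:", paste(miss, collapse = ", "))
    else if (any(object@table$has_fire & !is.finite(object@table$z90)) ||
             any(!object@table$has_fire & !is.na(object@table$z90)))
      "z90 must be present exactly for fire years"
    else TRUE
  })

# ---------------------------------------------------------------------------
# Results
# ---------------------------------------------------------------------------

#' TrendResult: slope, total change and uncertainty of a trend fit
#'
#' @slot slope trend slope (units per year).
#' @slot totalChange slope times the number of fire years.
#' @slot ciSlope 95\% CI of the slope (low, high).
#' @slot ciTotal 95\% CI of the total change.
#' @slot pValue two-sided p-value.
#' @slot method label of the fitting method.
#' @slot nYears number of years used.
#' @slot degenerate TRUE when the response was constant.
#' @export
setClass("TrendResult",
  representation(slope = "numeric", totalChange = "numeric",
                 ciSlope = "numeric", ciTotal = "numeric", pValue = "numeric",
                 method = "character", nYears = "integer",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@degenerate && length(object@ciSlope) == 2 &&
        all(is.finite(object@ciSlope)) &&
        (object@slope < object@ciSlope[1] - 1e-8 ||
         object@slope > object@ciSlope[2] + 1e-8))
      msg <- c(msg, "slope must lie inside its CI")
    if (length(msg)) msg else TRUE
  })

#' VelocityResult: elevational climate velocity of a climate variable
#'
#' @slot dvpdDt temporal trend(s), kPa per year (per cell).
#' @slot dvpdDe elevational gradient, kPa per metre (per ecoregion).
#' @slot velocity summary upslope-positive velocity, m per year.
#' @slot velocityCells per-cell velocities, m per year.
#' @slot totalDisplacement velocity times record length, m.
#' @slot recordYears record length in years.
#' @slot weakGradient TRUE when the gradient is below the threshold and the
#'   velocity is undefined.
#' @export
setClass("VelocityResult",
  representation(dvpdDt = "numeric", dvpdDe = "numeric", velocity = "numeric",
                 velocityCells = "numeric", totalDisplacement = "numeric",
                 recordYears = "numeric", weakGradient = "logical"),
  validity = function(object) {
    if (!object@weakGradient && is.finite(object@velocity) &&
        abs(object@totalDisplacement -
            object@velocity * object@recordYears) > 1e-6)
      "totalDisplacement must equal velocity * recordYears"
    else TRUE
  })

#' DecompositionResult: temperature share of a VPD trend
#'
#' @slot observedTrend observed warm-season VPD trend, kPa per year.
#' @slot temperatureOnlyTrend trend with relative humidity frozen at its
#'   day-of-year climatology, kPa per year.
#' @slot fractionTemperature ratio of the two trends.
#' @slot undefined TRUE when the observed trend is (numerically) zero.
#' @export
setClass("DecompositionResult",
  representation(observedTrend = "numeric",
                 temperatureOnlyTrend = "numeric",
                 fractionTemperature = "numeric", undefined = "logical"))

#' SensitivityFit: interannual fire-climate regression
#'
#' @slot slope metric units per kPa of VPD.
#' @slot intercept fitted intercept.
#' @slot r Pearson correlation.
#' @slot pValue two-sided p-value.
#' @slot method "type1" (OLS) or "type2" (standardized major axis).
#' @slot nYears paired years used.
#' @slot metric name of the fire metric.
#' @export
setClass("SensitivityFit",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 pValue = "numeric", method = "character", nYears = "integer",
                 metric = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nYears < 5L) msg <- c(msg, "at least 5 paired years required")
    if (object@method == "type2" && is.finite(object@r) && object@r != 0 &&
        sign(object@slope) != sign(object@r))
      msg <- c(msg, "type2 slope must carry the sign of r")
    if (length(msg)) msg else TRUE
  })

#' AttributionResult: VPD-driven change in a fire metric
#'
#' @slot vpdTotalChange VPD linear trend times record span (kPa).
#' @slot attributedChange sensitivity slope times vpdTotalChange.
#' @slot percentChange percent of the regression-fitted start-of-record
#'   value (NA when that base is not positive).
#' @slot fittedStart the fitted metric value at start-of-record trend-line
#'   VPD (the percent base).
#' @slot metric metric name.
#' @export
setClass("AttributionResult",
  representation(vpdTotalChange = "numeric", attributedChange = "numeric",
                 percentChange = "numeric", fittedStart = "numeric",
                 metric = "character"))

#' HypsometricResult: newly fire-exposed forest area
#'
#' @slot z90Start regression-predicted Z90 at start-of-record trend-line VPD (m).
#' @slot z90End same at end of record (m).
#' @slot exposedArea signed forest area between the two elevations (km^2).
#' @slot exposedFraction share of ecoregion forest area.
#' @slot clamped TRUE when a predicted elevation fell outside the forest
#'   elevation range and was clamped.
#' @export
setClass("HypsometricResult",
  representation(z90Start = "numeric", z90End = "numeric",
                 exposedArea = "numeric", exposedFraction = "numeric",
                 clamped = "logical"),
  validity = function(object) {
    if (object@z90End > object@z90Start && object@exposedArea < 0)
      "exposed area must be >= 0 when z90 increased"
    else if (abs(object@exposedFraction) > 1 + 1e-9)
      "exposed fraction must lie in [-1, 1]"
    else TRUE
  })

# ---------------------------------------------------------------------------
# Synthetic generator configs and ground truth
# ---------------------------------------------------------------------------

#' LandscapeConfig: synthetic DEM and forest-band parameters
#'
#' @slot nx,ny grid cell counts (>= 8 each).
#' @slot cellSize cell edge length in km.
#' @slot elevRange (min, max) elevation in m.
#' @slot reliefRoughness dimensionless 0-1 roughness of the DEM.
#' @slot forestBand (low, high) elevation band fully forested.
#' @slot taperWidth width (m) over which forest probability tapers to 0.
#' @slot seed RNG seed.
#' @export
setClass("LandscapeConfig",
  representation(nx = "integer", ny = "integer", cellSize = "numeric",
                 elevRange = "numeric", reliefRoughness = "numeric",
                 forestBand = "numeric", taperWidth = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nx < 8L || object@ny < 8L)
      msg <- c(msg, "grid must be at least 8x8")
    if (object@elevRange[1] > object@elevRange[2])
      msg <- c(msg, "elevRange must be ordered (min <= max)")
    if (object@taperWidth < 0) msg <- c(msg, "taperWidth must be >= 0")
    if (object@reliefRoughness < 0 || object@reliefRoughness > 1)
      msg <- c(msg, "reliefRoughness must lie in [0, 1]")
    if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname LandscapeConfig-class
#' @param nx,ny grid cell counts.
#' @param cellSize cell edge (km).
#' @param elevRange (min, max) elevation (m).
#' @param reliefRoughness roughness in [0, 1].
#' @param forestBand fully forested elevation band (m).
#' @param taperWidth taper width (m).
#' @param seed RNG seed.
#' @return A \linkS4class{LandscapeConfig}.
#' @export
landscapeConfig <- function(nx = 48L, ny = 48L, cellSize = 1,
                            elevRange = c(500, 3500), reliefRoughness = 0.3,
                            forestBand = c(900, 3200), taperWidth = 150,
                            seed = 1L) {
  new("LandscapeConfig", nx = as.integer(nx), ny = as.integer(ny),
      cellSize = as.numeric(cellSize), elevRange = as.numeric(elevRange),
      reliefRoughness = as.numeric(reliefRoughness),
      forestBand = as.numeric(forestBand),
      taperWidth = as.numeric(taperWidth), seed = as.integer(seed))
}

#' ClimateConfig: synthetic warm-season VPD field parameters
#'
#' VPD(cell, year) = vpdBase - lapse * E + trend * (year - start) + noise,
#' clipped at zero.
#'
#' @slot vpdBase kPa at zero elevation.
#' @slot lapse kPa per m by which VPD decreases with elevation (> 0).
#' @slot trend kPa per year.
#' @slot interannualSd sd of the shared year-to-year noise (kPa).
#' @slot spatialNoiseSd sd of the smoothed per-year spatial field (kPa).
#' @slot years (start, end) calendar years.
#' @slot seed RNG seed.
#' @export
setClass("ClimateConfig",
  representation(vpdBase = "numeric", lapse = "numeric", trend = "numeric",
                 interannualSd = "numeric", spatialNoiseSd = "numeric",
                 years = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lapse <= 0) msg <- c(msg, "lapse must be > 0")
    if (object@interannualSd < 0 || object@spatialNoiseSd < 0)
      msg <- c(msg, "noise sds must be >= 0")
    if (object@years[2] < object@years[1])
      msg <- c(msg, "end year must be >= start year")
    if (length(msg)) msg else TRUE
  })

#' @rdname ClimateConfig-class
#' @param vpdBase kPa at zero elevation.
#' @param lapse kPa per m (> 0).
#' @param trend kPa per year.
#' @param interannualSd kPa.
#' @param spatialNoiseSd kPa.
#' @param years (start, end) years.
#' @param seed RNG seed.
#' @return A \linkS4class{ClimateConfig}.
#' @export
climateConfig <- function(vpdBase = 2.2, lapse = 2e-4, trend = 1.78e-3,
                          interannualSd = 0.12, spatialNoiseSd = 0.05,
                          years = c(1984L, 2017L), seed = 1L) {
  new("ClimateConfig", vpdBase = as.numeric(vpdBase),
      lapse = as.numeric(lapse), trend = as.numeric(trend),
      interannualSd = as.numeric(interannualSd),
      spatialNoiseSd = as.numeric(spatialNoiseSd),
      years = as.integer(years), seed = as.integer(seed))
}

#' FlammabilityConfig: logistic flammability and ignition parameters
#'
#' A cell offered to a growing fire joins with probability
#' plogis(alpha + beta * VPD).
#'
#' @slot alpha log-odds intercept.
#' @slot beta log-odds per kPa of VPD (>= 0).
#' @slot ignitionsPerYear expected ignition count (Poisson mean).
#' @slot minFireCells minimum fire size retained (cells), emulating a
#'   405-ha perimeter floor.
#' @slot seed RNG seed.
#' @export
setClass("FlammabilityConfig",
  representation(alpha = "numeric", beta = "numeric",
                 ignitionsPerYear = "numeric", minFireCells = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
    if (object@ignitionsPerYear < 0)
      msg <- c(msg, "ignitionsPerYear must be >= 0")
    if (object@minFireCells < 1L) msg <- c(msg, "minFireCells must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname FlammabilityConfig-class
#' @param alpha log-odds intercept.
#' @param beta log-odds per kPa (>= 0).
#' @param ignitionsPerYear expected ignitions per year.
#' @param minFireCells minimum retained fire size (cells).
#' @param seed RNG seed.
#' @return A \linkS4class{FlammabilityConfig}.
#' @export
flammabilityConfig <- function(alpha = -25.2, beta = 15,
                               ignitionsPerYear = 3, minFireCells = 4L,
                               seed = 1L) {
  new("FlammabilityConfig", alpha = as.numeric(alpha), beta = as.numeric(beta),
      ignitionsPerYear = as.numeric(ignitionsPerYear),
      minFireCells = as.integer(minFireCells), seed = as.integer(seed))
}

#' SyntheticTruth: closed-form ground truth for parameter recovery
#'
#' @slot trueVelocity trend / lapse, m per year.
#' @slot trueZ90 named (by year) expected Z90 from direct per-cell
#'   burn-probability evaluation (m).
#' @slot excludedYears years flagged because every burn probability was zero.
#' @slot configs list of the configs used.
#' @export
setClass("SyntheticTruth",
  representation(trueVelocity = "numeric", trueZ90 = "numeric",
                 excludedYears = "integer", configs = "list"),
  validity = function(object) {
    if (!is.finite(object@trueVelocity)) "trueVelocity must be finite"
    else TRUE
  })

# ---------------------------------------------------------------------------
# Pipeline configuration and report bundle
# ---------------------------------------------------------------------------

#' RunConfig: full pipeline configuration
#'
#' @slot mode "synthetic" or "real".
#' @slot nEcoregions number of synthetic ecoregions.
#' @slot landscape template \linkS4class{LandscapeConfig}.
#' @slot climate template \linkS4class{ClimateConfig}.
#' @slot flammability template \linkS4class{FlammabilityConfig}.
#' @slot binWidth elevation bin width (m).
#' @slot tau quantile level for the trend regression.
#' @slot bootReps bootstrap replicates for the quantile-slope CI.
#' @slot qrMaxPoints per-year subsampling cap for the quantile regression.
#' @slot seed master seed; per-ecoregion seeds are derived from it.
#' @slot epochs list of two year vectors for epoch comparisons.
#' @slot bands elevation band edges (m).
#' @slot thresholds fixed elevation thresholds for burned-area-above (m).
#' @slot outDir output directory ("" keeps results in memory).
#' @slot paths named list of input paths (real mode).
#' @export
setClass("RunConfig",
  representation(mode = "character", nEcoregions = "integer",
                 landscape = "LandscapeConfig", climate = "ClimateConfig",
                 flammability = "FlammabilityConfig", binWidth = "numeric",
                 tau = "numeric", bootReps = "integer",
                 qrMaxPoints = "integer", seed = "integer",
                 epochs = "list", bands = "numeric", thresholds = "numeric",
                 outDir = "character", paths = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("synthetic", "real"))
      msg <- c(msg, "mode must be 'synthetic' or 'real'")
    if (object@tau <= 0 || object@tau >= 1)
      msg <- c(msg, "tau must lie in (0, 1)")
    if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
    if (length(object@epochs) != 2L)
      msg <- c(msg, "epochs must hold two year vectors")
    if (length(msg)) msg else TRUE
  })

#' ReportBundle: pipeline outputs
#'
#' @slot metrics per ecoregion-year fire metrics (data.frame).
#' @slot climate per ecoregion-year warm-season VPD (data.frame).
#' @slot trends per-ecoregion trend table (data.frame).
#' @slot velocity per-ecoregion velocity table (data.frame).
#' @slot attribution per-ecoregion attribution table (data.frame).
#' @slot summary cross-ecoregion summary (list).
#' @slot manifest run manifest (list): config, seed, versions, row counts.
#' @slot outDir directory the tables were written to ("" if in-memory).
#' @export
setClass("ReportBundle",
  representation(metrics = "data.frame", climate = "data.frame",
                 trends = "data.frame", velocity = "data.frame",
                 attribution = "data.frame", summary = "list",
                 manifest = "list", outDir = "character"))
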