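# Fire-climate sensitivity regressions, VPD-driven change estimates and the
# hypsometric estimate of newly fire-exposed forest area.

#' Interannual fire-climate sensitivity regression
#'
#' Type I is ordinary least squares of the fire metric on warm-season VPD.
#' Type II is the standardized major axis: slope = sign(r) sd(metric)/sd(VPD),
#' allowing error in both variables. Pairs with a missing metric (fire-free
#' years for Z90) are dropped; BA90 series should carry zeros for fire-free
#' years instead.
#'
#' @param vpd annual warm-season VPD series (kPa).
#' @param metric matching annual fire metric series (NA for fire-free years
#'   when the metric is undefined there).
#' @param method "type1" (default) or "type2".
#' @param metricName label stored in the fit.
#' @return A \linkS4class{SensitivityFit}.
#' @export
fitSensitivity <- function(vpd, metric, method = c("type1", "type2"),
                           metricName = "metric") {
  method <- match.arg(method)
  stopifnot(length(vpd) == length(metric))
  ok <- is.finite(vpd) & is.finite(metric)
  x <- vpd[ok]
  y <- metric[ok]
  if (length(x) < 5L) stop("at least 5 paired fire years are required")
  if (sd(x) == 0) stop("zero VPD variance: sensitivity unidentifiable")
  r <- if (sd(y) == 0) 0 else cor(x, y)
  if (method == "type1") {
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    p <- summary(fit)$coefficients[2, 4]
  } else {
    slope <- sign(r) * sd(y) / sd(x)
    if (r == 0) slope <- 0
    intercept <- mean(y) - slope * mean(x)
    p <- if (sd(y) == 0) NA_real_ else cor.test(x, y)$p.value
  }
  new("SensitivityFit", slope = slope, intercept = intercept, r = r,
      pValue = p, method = method, nYears = length(x),
      metric = metricName)
}

#' VPD-driven change in a fire metric
#'
#' The attributed change is the product of the VPD linear trend over the
#' record and the interannual VPD-metric sensitivity. The percent change is
#' relative to the regression-fitted metric value at the start-of-record
#' trend-line VPD; when that base is not positive the percent is flagged
#' undefined while the absolute change is still reported.
#'
#' @param fit a \linkS4class{SensitivityFit} from the same ecoregion.
#' @param vpd annual warm-season VPD series.
#' @param years matching years.
#' @param span record span in years (defaults to the number of years in the
#'   record).
#' @return An \linkS4class{AttributionResult}.
#' @export
vpdDrivenChange <- function(fit, vpd, years, span = NULL) {
  stopifnot(is(fit, "SensitivityFit"), length(vpd) == length(years))
  if (is.null(span)) span <- length(unique(years))
  tfit <- lm(vpd ~ years)
  vpdTrend <- unname(coef(tfit)[2])
  vpdTotal <- vpdTrend * span
  attributed <- fit@slope * vpdTotal
  vpdStart <- unname(coef(tfit)[1]) + vpdTrend * min(years)
  base <- fit@intercept + fit@slope * vpdStart
  pct <- if (base > 0) 100 * attributed / base else NA_real_
  new("AttributionResult", vpdTotalChange = vpdTotal,
      attributedChange = attributed, percentChange = pct,
      fittedStart = base, metric = fit@metric)
}

#' Hypsometric estimate of newly fire-exposed forest area
#'
#' Applies the VPD-Z90 regression to the trend-line VPD of the first and
#' last year of the record and integrates the ecoregion's forest hypsometry
#' between the two predicted elevations: the forest area that moved from
#' above to below the normalized burn distribution's 90th percentile.
#' Predictions outside the forest elevation range are clamped to the range
#' ends and flagged.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param fit a \linkS4class{SensitivityFit} of Z90 on VPD.
#' @param vpd annual warm-season VPD series.
#' @param years matching years.
#' @return A \linkS4class{HypsometricResult}; the exposed area is signed
#'   (negative when the predicted Z90 declined).
#' @export
hypsometricExposure <- function(grid, fit, vpd, years) {
  stopifnot(is(grid, "ForestGrid"), is(fit, "SensitivityFit"),
            length(vpd) == length(years))
  tfit <- lm(vpd ~ years)
  vAt <- function(y) unname(coef(tfit)[1] + coef(tfit)[2] * y)
  z0 <- fit@intercept + fit@slope * vAt(min(years))
  z1 <- fit@intercept + fit@slope * vAt(max(years))
  forest <- forestMask(grid)
  e <- elevations(grid)[forest]
  area <- cellAreas(grid)[forest]
  rng <- range(e)
  clamp <- function(z) min(max(z, rng[1]), rng[2])
  clamped <- z0 < rng[1] || z0 > rng[2] || z1 < rng[1] || z1 > rng[2]
  z0c <- clamp(z0)
  z1c <- clamp(z1)
  if (abs(z1c - z0c) < 1e-9) z1c <- z0c  # numerically flat trend line
  lo <- min(z0c, z1c)
  hi <- max(z0c, z1c)
  a <- sum(area[e > lo & e <= hi])
  signed <- if (z1c >= z0c) a else -a
  new("HypsometricResult", z90Start = z0c, z90End = z1c,
      exposedArea = signed, exposedFraction = signed / sum(area),
      clamped = clamped)
}

#' Aggregate per-ecoregion results
#'
#' Medians across ecoregions for elevation- and velocity-scaled quantities,
#' sums for areas, and counts of ecoregions significant at the 5\% level.
#' Undefined (NA) entries are excluded from medians with a logged count.
#'
#' @param df data.frame with one row per ecoregion.
#' @param medianCols columns to summarise by median.
#' @param sumCols columns to summarise by sum.
#' @param pCols p-value columns to count significance (p < 0.05).
#' @return list of summaries with an \code{nExcluded} count per median
#'   column.
#' @export
aggregateEcoregions <- function(df, medianCols = character(),
                                sumCols = character(),
                                pCols = character()) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  med <- lapply(medianCols, function(cn) {
    v <- df[[cn]]
    list(median = median(v, na.rm = TRUE), nExcluded = sum(!is.finite(v)))
  })
  names(med) <- medianCols
  tot <- lapply(sumCols, function(cn) sum(df[[cn]], na.rm = TRUE))
  names(tot) <- sumCols
  sig <- lapply(pCols, function(cn) sum(df[[cn]] < 0.05, na.rm = TRUE))
  names(sig) <- pCols
  list(nEcoregions = nrow(df), medians = med, totals = tot,
       nSignificant = sig)
}
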