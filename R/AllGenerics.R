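#' Accessors for fireElev classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("elevations", function(x) standardGeneric("elevations"))
#' @rdname accessors
#' @export
setMethod("elevations", "ForestGrid", function(x) x@elevation)

#' @rdname accessors
#' @export
setGeneric("forestMask", function(x) standardGeneric("forestMask"))
#' @rdname accessors
#' @export
setMethod("forestMask", "ForestGrid", function(x) x@forest)

#' @rdname accessors
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))
#' @rdname accessors
#' @export
setMethod("cellAreas", "ForestGrid", function(x) x@cellArea)

#' @rdname accessors
#' @export
setGeneric("ecoregionId", function(x) standardGeneric("ecoregionId"))
#' @rdname accessors
#' @export
setMethod("ecoregionId", "ForestGrid", function(x) x@ecoregion)

#' @rdname accessors
#' @export
setGeneric("forestArea", function(x) standardGeneric("forestArea"))
#' @rdname accessors
#' @export
setMethod("forestArea", "ForestGrid", function(x) sum(x@cellArea[x@forest]))

#' @rdname accessors
#' @export
setGeneric("burnMask", function(x) standardGeneric("burnMask"))
#' @rdname accessors
#' @export
setMethod("burnMask", "AnnualBurn", function(x) x@burn)

#' @rdname accessors
#' @export
setGeneric("burnYear", function(x) standardGeneric("burnYear"))
#' @rdname accessors
#' @export
setMethod("burnYear", "AnnualBurn", function(x) x@year)

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
#' @rdname accessors
#' @export
setMethod("metricsTable", "FireMetricsSeries", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("isEmpty", function(x) standardGeneric("isEmpty"))
#' @rdname accessors
#' @export
setMethod("isEmpty", "NormalizedElevDist", function(x) x@empty)

#' @rdname accessors
#' @export
setGeneric("trueVelocity", function(x) standardGeneric("trueVelocity"))
#' @rdname accessors
#' @export
setMethod("trueVelocity", "SyntheticTruth", function(x) x@trueVelocity)

#' @rdname accessors
#' @export
setGeneric("trueZ90", function(x) standardGeneric("trueZ90"))
#' @rdname accessors
#' @export
setMethod("trueZ90", "SyntheticTruth", function(x) x@trueZ90)

setMethod("show", "ForestGrid", function(object) {
  d <- dim(object@elevation)
  cat("ForestGrid [", object@ecoregion, "] ", d[1], "x", d[2], " cells, ",
      sum(object@forest), " forest cells (",
      format(forestArea(object), digits = 5), " km^2), elevation ",
      format(min(object@elevation), digits = 5), "-",
      format(max(object@elevation), digits = 5), " m\n", sep = "")
})

setMethod("show", "AnnualBurn", function(object) {
  cat("AnnualBurn ", object@year, ": ", sum(object@burn), " burned cells",
      if (object@severityFiltered) " (severity-filtered)" else "", "\n",
      sep = "")
})

setMethod("show", "NormalizedElevDist", function(object) {
  if (object@empty) {
    cat("NormalizedElevDist [", object@ecoregion, " ", object@year,
        "]: no burned forest cells (fire-free year)\n", sep = "")
  } else {
    cat("NormalizedElevDist [", object@ecoregion, " ", object@year, "]: ",
        object@nBurnedCells, " burned cells, ",
        format(object@totalBurnedArea, digits = 5), " km^2, Z90 = ",
        format(zQuantile(object, 0.9), digits = 6), " m\n", sep = "")
  }
})

setMethod("show", "FireMetricsSeries", function(object) {
  cat("FireMetricsSeries: ", nrow(object@table), " ecoregion-years, ",
      sum(object@table$has_fire), " with fire\n", sep = "")
  print(head(object@table, 5))
})

setMethod("show", "TrendResult", function(object) {
  cat("TrendResult (", object@method, "): slope ",
      format(object@slope, digits = 4), "/y, total change ",
      format(object@totalChange, digits = 4), " over ", object@nYears,
      " fire years, 95% CI [", format(object@ciTotal[1], digits = 4), ", ",
      format(object@ciTotal[2], digits = 4), "], p = ",
      format(object@pValue, digits = 3),
      if (object@degenerate) " (degenerate)" else "", "\n", sep = "")
})

setMethod("show", "VelocityResult", function(object) {
  if (object@weakGradient) {
    cat("VelocityResult: undefined (gradient below threshold)\n")
  } else {
    cat("VelocityResult: ", format(object@velocity, digits = 4),
        " m/y upslope, ", format(object@totalDisplacement, digits = 4),
        " m over ", object@recordYears, " y (dVPD/dt = ",
        format(median(object@dvpdDt), digits = 4), " kPa/y, dVPD/dE = ",
        format(object@dvpdDe, digits = 4), " kPa/m)\n", sep = "")
  }
})

setMethod("show", "SensitivityFit", function(object) {
  cat("SensitivityFit (", object@method, ", ", object@metric, "): slope ",
      format(object@slope, digits = 4), " per kPa, r = ",
      format(object@r, digits = 3), ", p = ",
      format(object@pValue, digits = 3), ", n = ", object@nYears, "\n",
      sep = "")
})

setMethod("show", "AttributionResult", function(object) {
  cat("AttributionResult (", object@metric, "): VPD change ",
      format(object@vpdTotalChange, digits = 4), " kPa -> ",
      format(object@attributedChange, digits = 4),
      if (is.na(object@percentChange)) " (percent undefined)"
      else paste0(" (", format(object@percentChange, digits = 4), "%)"),
      "\n", sep = "")
})

setMethod("show", "HypsometricResult", function(object) {
  cat("HypsometricResult: Z90 ", format(object@z90Start, digits = 6), " -> ",
      format(object@z90End, digits = 6), " m, exposed area ",
      format(object@exposedArea, digits = 5), " km^2 (",
      format(100 * object@exposedFraction, digits = 3), "% of forest)",
      if (object@clamped) " [clamped]" else "", "\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: velocity ", format(object@trueVelocity, digits = 4),
      " m/y, ", length(object@trueZ90), " yearly oracle Z90 values\n",
      sep = "")
})

setMethod("show", "DecompositionResult", function(object) {
  cat("DecompositionResult: observed trend ",
      format(object@observedTrend, digits = 4), " kPa/y, T-only ",
      format(object@temperatureOnlyTrend, digits = 4), " kPa/y, fraction ",
      if (object@undefined) "undefined"
      else format(object@fractionTemperature, digits = 3), "\n", sep = "")
})
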