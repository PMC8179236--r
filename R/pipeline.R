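# Pipeline orchestration: synthetic simulation or real-data ingest, the
# elevational distribution stage, trend analysis, climate metrics,
# attribution and reporting.

#' Build a pipeline configuration
#'
#' The synthetic defaults describe a 15-ecoregion, 1984-2017 study on
#' 48 x 48 km grids with a prescribed VPD lapse (2e-4 kPa/m) and trend
#' (1.78e-3 kPa/y, an elevational VPD velocity of 8.9 m/y) and a logistic
#' flammability that increases with VPD.
#'
#' @param mode "synthetic" or "real".
#' @param nEcoregions number of synthetic ecoregions.
#' @param landscape,climate,flammability template configs; per-ecoregion
#'   seeds are derived from the master \code{seed}.
#' @param binWidth elevation bin width (m).
#' @param tau quantile level for the Z90 trend.
#' @param bootReps bootstrap replicates.
#' @param qrMaxPoints per-year subsampling cap for the quantile regression.
#' @param seed master seed.
#' @param epochs list of two year vectors for epoch comparisons.
#' @param bands elevation band edges (m).
#' @param thresholds fixed burned-area-above thresholds (m).
#' @param outDir output directory ("" keeps results in memory).
#' @param paths named list of real-mode input paths.
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(mode = "synthetic", nEcoregions = 15L,
                      landscape = landscapeConfig(),
                      climate = climateConfig(),
                      flammability = flammabilityConfig(),
                      binWidth = 50, tau = 0.9, bootReps = 1000L,
                      qrMaxPoints = 500L, seed = 1L,
                      epochs = list(1984:2000, 2001:2017),
                      bands = c(-Inf, 1000, 1500, 2000, 2500, 3000, Inf),
                      thresholds = c(2000, 2500, 3000),
                      outDir = "", paths = list()) {
  new("RunConfig", mode = mode, nEcoregions = as.integer(nEcoregions),
      landscape = landscape, climate = climate, flammability = flammability,
      binWidth = as.numeric(binWidth), tau = as.numeric(tau),
      bootReps = as.integer(bootReps),
      qrMaxPoints = as.integer(qrMaxPoints), seed = as.integer(seed),
      epochs = epochs, bands = as.numeric(bands),
      thresholds = as.numeric(thresholds), outDir = outDir, paths = paths)
}

# Re-seed a config template for ecoregion k under a master seed.
reseed <- function(cfg, master, k, offset) {
  cfg@seed <- deriveSeed(master, 3L * k + offset)
  cfg
}

#' Simulate one synthetic ecoregion
#'
#' @param cfg a \linkS4class{RunConfig} in synthetic mode.
#' @param k ecoregion index (drives seed derivation).
#' @return list with the grid, the VPD array, the burn list and the
#'   ground-truth oracle.
#' @export
simulateEcoregion <- function(cfg, k = 1L) {
  stopifnot(is(cfg, "RunConfig"), cfg@mode == "synthetic")
  land <- reseed(cfg@landscape, cfg@seed, k, 0L)
  clim <- reseed(cfg@climate, cfg@seed, k, 1L)
  flam <- reseed(cfg@flammability, cfg@seed, k, 2L)
  grid <- generateLandscape(land, ecoregion = sprintf("SYN%02d", k))
  vpd <- generateClimate(grid, clim)
  burns <- generateFires(grid, vpd, flam)
  truth <- trueZ90Oracle(grid, vpd, flam, clim, binWidth = cfg@binWidth)
  list(grid = grid, vpd = vpd, burns = burns, truth = truth,
       configs = list(landscape = land, climate = clim,
                      flammability = flam))
}

# Run one stage with a labelled error.
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: synthetic generation (or real-data ingest), normalized elevational
#' burn distributions and fire metrics, trend analysis (quantile trend of
#' Z90, Mann-Kendall tests, epoch band comparisons, VPD terciles and
#' correlations), climate metrics (velocity), attribution (sensitivity
#' regressions, VPD-driven changes, hypsometric exposure) and a
#' cross-ecoregion summary. In synthetic mode a fixed master seed yields
#' byte-identical outputs.
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @param verbose print per-stage progress.
#' @return A \linkS4class{ReportBundle}.
#' @export
runPipeline <- function(cfg, verbose = FALSE) {
  stopifnot(is(cfg, "RunConfig"))
  validObject(cfg)
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  outDir <- cfg@outDir
  if (nzchar(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  onFail <- function(e) {
    if (nzchar(outDir))
      writeLines(conditionMessage(e), file.path(outDir, "RUN.failed"))
    stop(e)
  }
  tryCatch({
    ecoData <- withStage("ingest", {
      if (cfg@mode == "synthetic") {
        lapply(seq_len(cfg@nEcoregions), function(k) simulateEcoregion(cfg, k))
      } else {
        list(ingestReal(cfg@paths, cfg = cfg))
      }
    })
    say("ingest: ", length(ecoData), " ecoregions")

    metricsList <- list()
    climateList <- list()
    trendRows <- list()
    velRows <- list()
    attrRows <- list()
    for (i in seq_along(ecoData)) {
      ed <- ecoData[[i]]
      grid <- ed$grid
      eco <- ecoregionId(grid)
      hasGriddedVpd <- !is.null(ed$vpd)
      years <- if (hasGriddedVpd) as.integer(dimnames(ed$vpd)[[3]])
               else vapply(ed$burns, burnYear, integer(1))

      dists <- withStage("elev_dist", {
        dens <- forestElevationDensity(grid, cfg@binWidth)
        lapply(ed$burns, function(b)
          normalizedBurnDistribution(grid, b, cfg@binWidth, density = dens))
      })
      fm <- withStage("elev_dist",
                      fireMetricsSeries(grid, ed$burns, cfg@binWidth,
                                        cfg@thresholds, cfg@bands))
      tab <- metricsTable(fm)
      metricsList[[i]] <- tab

      vpdAnnual <- if (hasGriddedVpd) {
        apply(ed$vpd, 3, mean)  # ecoregion warm-season average
      } else if (!is.null(ed$climate)) {
        setNames(ed$climate$vpd_kpa, ed$climate$year)[as.character(years)]
      } else {
        rep(NA_real_, length(years))
      }
      climateList[[i]] <- data.frame(ecoregion = eco, year = years,
                                     vpd_kpa = as.numeric(vpdAnnual))
      hasVpdSeries <- all(is.finite(vpdAnnual))

      trendRows[[i]] <- withStage("trend_analysis", {
        fireYears <- sum(tab$has_fire)
        tr <- if (fireYears >= 5)
          z90Trend(dists, tau = cfg@tau, nBoot = cfg@bootReps,
                   seed = deriveSeed(cfg@seed, 1000L + i),
                   maxPointsPerYear = cfg@qrMaxPoints)
        else NULL
        mkZ <- if (fireYears >= 4) mannKendall(tab$z90[tab$has_fire]) else NULL
        mkB <- mannKendall(tab$ba90)
        topBand <- names(tab)[grepl("^band_gt_", names(tab))][1]
        ep <- epochPercentChange(tab[[topBand]], tab$year,
                                 cfg@epochs[[1]], cfg@epochs[[2]])
        corZ <- if (hasVpdSeries && sum(is.finite(tab$z90)) >= 4)
          interannualCorrelation(vpdAnnual, tab$z90)
        else list(r = NA, p.value = NA)
        corB <- if (hasVpdSeries && sum(is.finite(tab$ba90)) >= 4)
          interannualCorrelation(vpdAnnual, tab$ba90)
        else list(r = NA, p.value = NA)
        data.frame(ecoregion = eco, n_fire_years = fireYears,
                   z90_slope_m_per_y = if (is.null(tr)) NA else tr@slope,
                   z90_total_change_m = if (is.null(tr)) NA else tr@totalChange,
                   z90_ci_low_m = if (is.null(tr)) NA else tr@ciTotal[1],
                   z90_ci_high_m = if (is.null(tr)) NA else tr@ciTotal[2],
                   z90_trend_p = if (is.null(tr)) NA else tr@pValue,
                   z90_mk_p = if (is.null(mkZ)) NA else mkZ$p.value,
                   ba90_mk_p = mkB$p.value,
                   top_band_epoch_pct = ep$percent,
                   vpd_z90_r = corZ$r, vpd_z90_p = corZ$p.value,
                   vpd_ba90_r = corB$r, vpd_ba90_p = corB$p.value)
      })

      velRows[[i]] <- withStage("climate_metrics", {
        if (hasGriddedVpd) {
          dvdt <- temporalTrend(ed$vpd, years)
          clim <- apply(ed$vpd, c(1, 2), mean)
          dvde <- elevationalGradient(clim, grid)
          vel <- elevationalVelocity(as.numeric(dvdt), dvde, length(years))
          data.frame(ecoregion = eco,
                     dvpd_dt_kpa_per_y = median(as.numeric(dvdt)),
                     dvpd_de_kpa_per_m = dvde,
                     velocity_m_per_y = vel@velocity,
                     displacement_m = vel@totalDisplacement,
                     weak_gradient = vel@weakGradient)
        } else {
          data.frame(ecoregion = eco, dvpd_dt_kpa_per_y = NA,
                     dvpd_de_kpa_per_m = NA, velocity_m_per_y = NA,
                     displacement_m = NA, weak_gradient = NA)
        }
      })

      attrRows[[i]] <- withStage("attribution", {
        fitZ <- if (hasVpdSeries && sum(tab$has_fire) >= 5)
          fitSensitivity(vpdAnnual, tab$z90, "type1", "z90") else NULL
        fitB <- if (hasVpdSeries)
          fitSensitivity(vpdAnnual, tab$ba90, "type1", "ba90") else NULL
        attZ <- if (!is.null(fitZ)) vpdDrivenChange(fitZ, vpdAnnual, years)
                else NULL
        attB <- if (!is.null(fitB)) vpdDrivenChange(fitB, vpdAnnual, years)
                else NULL
        hyp <- if (!is.null(fitZ)) hypsometricExposure(grid, fitZ, vpdAnnual,
                                                       years) else NULL
        data.frame(ecoregion = eco,
                   z90_vpd_slope_m_per_kpa = if (is.null(fitZ)) NA
                                             else fitZ@slope,
                   z90_vpd_p = if (is.null(fitZ)) NA else fitZ@pValue,
                   vpd_change_kpa = if (is.null(attB)) NA
                                    else attB@vpdTotalChange,
                   z90_attr_change_m = if (is.null(attZ)) NA
                                       else attZ@attributedChange,
                   ba90_attr_change_km2 = if (is.null(attB)) NA
                                          else attB@attributedChange,
                   ba90_attr_pct = if (is.null(attB)) NA
                                   else attB@percentChange,
                   exposed_area_km2 = if (is.null(hyp)) NA
                                      else hyp@exposedArea,
                   exposed_fraction = if (is.null(hyp)) NA
                                      else hyp@exposedFraction,
                   forest_area_km2 = forestArea(grid))
      })
      say("ecoregion ", eco, ": ", nrow(tab), " years, ",
          sum(tab$has_fire), " fire years")
    }

    metrics <- do.call(rbind, metricsList)
    climate <- do.call(rbind, climateList)
    trends <- do.call(rbind, trendRows)
    velocity <- do.call(rbind, velRows)
    attribution <- do.call(rbind, attrRows)

    summary <- withStage("report", {
      aggregateEcoregions(
        cbind(trends, velocity[, -1], attribution[, -1]),
        medianCols = c("z90_total_change_m", "z90_ci_low_m", "z90_ci_high_m",
                       "velocity_m_per_y", "displacement_m",
                       "z90_attr_change_m", "ba90_attr_pct",
                       "exposed_fraction"),
        sumCols = c("ba90_attr_change_km2", "exposed_area_km2",
                    "forest_area_km2"),
        pCols = c("z90_mk_p", "vpd_z90_p", "vpd_ba90_p"))
    })

    manifest <- list(
      package = "fireElev",
      version = as.character(utils::packageVersion("fireElev")),
      mode = cfg@mode, seed = cfg@seed, nEcoregions = length(ecoData),
      bootReps = cfg@bootReps, binWidth = cfg@binWidth, tau = cfg@tau,
      rows = list(metrics = nrow(metrics), climate = nrow(climate),
                  trends = nrow(trends), velocity = nrow(velocity),
                  attribution = nrow(attribution)))

    if (nzchar(outDir)) {
      withStage("report", {
        write.csv(metrics, file.path(outDir, "metrics_series.csv"),
                  row.names = FALSE, na = "NA")
        write.csv(climate, file.path(outDir, "climate_series.csv"),
                  row.names = FALSE, na = "NA")
        write.csv(trends, file.path(outDir, "trends.csv"),
                  row.names = FALSE, na = "NA")
        write.csv(velocity, file.path(outDir, "velocity.csv"),
                  row.names = FALSE, na = "NA")
        write.csv(attribution, file.path(outDir, "attribution.csv"),
                  row.names = FALSE, na = "NA")
        yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
        writeLines(log, file.path(outDir, "run.log"))
      })
    }
    new("ReportBundle", metrics = metrics, climate = climate,
        trends = trends, velocity = velocity, attribution = attribution,
        summary = summary, manifest = manifest, outDir = outDir)
  }, error = onFail)
}

#' Ingest real-mode inputs
#'
#' Reads a DEM and forest mask as ASCII grids, burn inputs either as GeoJSON
#' perimeters (with a \code{year} property, optional \code{area_ha} floor)
#' or as per-year severity rasters plus an explicit severity class mapping,
#' and an optional daily climate CSV
#' (columns date, tmax, tmin, rhmax, rhmin or date, vpd).
#'
#' @param paths named list: \code{dem}, \code{forest}, and either
#'   \code{burns_geojson} or \code{burn_rasters} (named by year) with
#'   \code{severity_map} (data.frame or CSV path with columns code, retain);
#'   optionally \code{climate_csv}, \code{ecoregion}, \code{min_fire_ha}.
#' @param cfg optional \linkS4class{RunConfig} (for bin width etc.).
#' @return list with \code{grid}, \code{burns}, \code{vpd} (array, one layer
#'   per year, if climate given) and \code{climate} data.frame.
#' @export
ingestReal <- function(paths, cfg = NULL) {
  stopifnot(!is.null(paths$dem), !is.null(paths$forest))
  dem <- readAsciiGrid(paths$dem)
  fmask <- readAsciiGrid(paths$forest)
  if (!all(dim(dem$matrix) == dim(fmask$matrix)))
    stop("grid misalignment between layers 'dem' and 'forest': ",
         paste(dim(dem$matrix), collapse = "x"), " vs ",
         paste(dim(fmask$matrix), collapse = "x"))
  cellKm <- dem$cellsize / 1000
  grid <- ForestGrid(dem$matrix, fmask$matrix > 0, cellArea = cellKm^2,
                     ecoregion = paths$ecoregion %||% "REAL")
  minHa <- as.numeric(paths$min_fire_ha %||% 405)
  burns <- NULL
  if (!is.null(paths$burns_geojson)) {
    burns <- readBurnsGeoJSON(paths$burns_geojson, nrow(dem$matrix),
                              ncol(dem$matrix), dem$xll, dem$yll,
                              dem$cellsize, minAreaHa = minHa)
  } else if (!is.null(paths$burn_rasters)) {
    sm <- paths$severity_map
    if (is.null(sm))
      stop("burn rasters require an explicit severity_map (code, retain)")
    if (is.character(sm)) sm <- read.csv(sm)
    burns <- lapply(names(paths$burn_rasters), function(y) {
      r <- readAsciiGrid(paths$burn_rasters[[y]])$matrix
      codes <- sort(unique(as.numeric(r[is.finite(r) & r != 0])))
      unknown <- setdiff(codes, sm$code)
      if (length(unknown))
        stop("unknown severity classes: ", paste(unknown, collapse = ", "),
             " (observed classes: ", paste(codes, collapse = ", "), ")")
      retain <- sm$code[sm$retain %in% c(TRUE, 1)]
      mask <- matrix(r %in% retain, nrow(r), ncol(r))
      AnnualBurn(as.integer(y), mask, severityFiltered = TRUE)
    })
  } else {
    stop("either burns_geojson or burn_rasters must be given")
  }
  climate <- NULL
  vpd <- NULL
  if (!is.null(paths$climate_csv)) {
    cc <- read.csv(paths$climate_csv)
    if (all(c("tmax", "tmin", "rhmax", "rhmin") %in% names(cc))) {
      daily <- vpdFromTRH(cc$tmax, cc$tmin, cc$rhmax, cc$rhmin)
      ann <- warmSeasonMean(as.Date(cc$date), daily)
    } else if ("vpd" %in% names(cc)) {
      ann <- warmSeasonMean(as.Date(cc$date), cc$vpd)
    } else {
      stop("climate CSV must carry tmax/tmin/rhmax/rhmin or vpd columns")
    }
    climate <- data.frame(ecoregion = ecoregionId(grid),
                          year = as.integer(names(ann)),
                          vpd_kpa = as.numeric(ann))
  }
  list(grid = grid, burns = burns, vpd = vpd, climate = climate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
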