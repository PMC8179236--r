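# Formats: plain-text ESRI ASCII grids for rasters, GeoJSON for burn
# perimeters, CSV for tables, YAML for configuration.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m numeric or logical matrix (row 1 is the top raster row).
#' @param path output path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize cell size in coordinate units.
#' @param nodata nodata marker.
#' @export
writeAsciiGrid <- function(m, path, xll = 0, yll = 0, cellsize = 1000,
                           nodata = -9999) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  m[!is.finite(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(xll, scientific = FALSE)),
           paste("yllcorner", format(yll, scientific = FALSE)),
           paste("cellsize", format(cellsize, scientific = FALSE)),
           paste("NODATA_value", nodata))
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               digits = 15,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input path.
#' @return list with \code{matrix} (nodata as NA), \code{xll}, \code{yll},
#'   \code{cellsize}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  list(matrix = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write burn masks as GeoJSON perimeters
#'
#' Each year becomes one feature holding a MultiPolygon of the burned cells'
#' square outlines, with a \code{year} property. Coordinates are grid
#' coordinates (lower-left origin, \code{cellsize} spacing).
#'
#' @param burns list of \linkS4class{AnnualBurn}.
#' @param path output path.
#' @param xll,yll grid lower-left corner.
#' @param cellsize cell edge in coordinate units.
#' @export
writeBurnsGeoJSON <- function(burns, path, xll = 0, yll = 0, cellsize = 1000) {
  features <- lapply(burns, function(b) {
    mask <- burnMask(b)
    nr <- nrow(mask)
    idx <- which(mask, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(idx)), function(k) {
      r <- idx[k, 1]
      cc <- idx[k, 2]
      x0 <- xll + (cc - 1) * cellsize
      y0 <- yll + (nr - r) * cellsize
      list(list(
        c(x0, y0), c(x0 + cellsize, y0), c(x0 + cellsize, y0 + cellsize),
        c(x0, y0 + cellsize), c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(year = burnYear(b),
                           n_cells = sum(mask)),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  features <- features[vapply(features,
                              function(f) f$properties$n_cells > 0,
                              logical(1))]
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON burn perimeters and rasterize them onto a grid
#'
#' Features must carry a \code{year} property; Polygon and MultiPolygon
#' geometries are supported. A cell burns in a year when its centre falls
#' inside any of that year's rings (even-odd rule). Features with an
#' \code{area_ha} property below \code{minAreaHa} are excluded, mirroring a
#' large-fire perimeter floor.
#'
#' @param path GeoJSON path.
#' @param nrows,ncols grid shape.
#' @param xll,yll,cellsize grid geometry.
#' @param minAreaHa minimum fire area in hectares (applied only when the
#'   property is present).
#' @return list of \linkS4class{AnnualBurn}, one per year present.
#' @export
readBurnsGeoJSON <- function(path, nrows, ncols, xll = 0, yll = 0,
                             cellsize = 1000, minAreaHa = 0) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  cx <- xll + (seq_len(ncols) - 0.5) * cellsize
  cy <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize
  feats <- gj$features
  years <- vapply(feats, function(f) as.integer(f$properties$year),
                  integer(1))
  out <- lapply(sort(unique(years)), function(y) {
    mask <- matrix(FALSE, nrows, ncols)
    for (f in feats[years == y]) {
      a <- f$properties$area_ha
      if (!is.null(a) && as.numeric(a) < minAreaHa) next
      geom <- f$geometry
      polys <- switch(geom$type,
                      Polygon = list(geom$coordinates),
                      MultiPolygon = geom$coordinates,
                      stop("unsupported geometry type: ", geom$type))
      for (poly in polys) {
        # even-odd across a polygon's rings (outer ring minus holes),
        # then union across polygons and features
        insideP <- matrix(FALSE, nrows, ncols)
        for (ring in poly) {
          px <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
          py <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
          for (r in seq_len(nrows)) {
            inside <- pointInRing(cx, rep(cy[r], ncols), px, py)
            insideP[r, ] <- xor(insideP[r, ], inside)
          }
        }
        mask <- mask | insideP
      }
    }
    AnnualBurn(y, mask, severityFiltered = TRUE)
  })
  out
}

# Even-odd ray casting for vectors of points against one ring.
pointInRing <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Write / read a fire metrics table as CSV
#'
#' UTF-8, comma separated, header row, \code{NA} for undefined values.
#'
#' @param x a \linkS4class{FireMetricsSeries} or plain data.frame.
#' @param path CSV path.
#' @export
writeFireMetricsCSV <- function(x, path) {
  df <- if (is(x, "FireMetricsSeries")) metricsTable(x) else x
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeFireMetricsCSV
#' @export
readFireMetricsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  new("FireMetricsSeries", table = df)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return A \linkS4class{RunConfig}.
#' @export
readRunConfigYAML <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("mode", "nEcoregions", "binWidth", "tau", "bootReps",
               "qrMaxPoints", "seed", "bands", "thresholds", "outDir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$epochs)) args$epochs <- lapply(y$epochs, as.integer)
  if (!is.null(y$landscape))
    args$landscape <- do.call(landscapeConfig, y$landscape)
  if (!is.null(y$climate)) {
    if (!is.null(y$climate$years)) y$climate$years <- as.integer(y$climate$years)
    args$climate <- do.call(climateConfig, y$climate)
  }
  if (!is.null(y$flammability))
    args$flammability <- do.call(flammabilityConfig, y$flammability)
  if (!is.null(y$paths)) args$paths <- y$paths
  do.call(runConfig, args)
}

#' @rdname readRunConfigYAML
#' @param cfg a \linkS4class{RunConfig}.
#' @export
writeRunConfigYAML <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  y <- list(
    mode = cfg@mode, nEcoregions = cfg@nEcoregions,
    landscape = list(nx = cfg@landscape@nx, ny = cfg@landscape@ny,
                     cellSize = cfg@landscape@cellSize,
                     elevRange = cfg@landscape@elevRange,
                     reliefRoughness = cfg@landscape@reliefRoughness,
                     forestBand = cfg@landscape@forestBand,
                     taperWidth = cfg@landscape@taperWidth,
                     seed = cfg@landscape@seed),
    climate = list(vpdBase = cfg@climate@vpdBase, lapse = cfg@climate@lapse,
                   trend = cfg@climate@trend,
                   interannualSd = cfg@climate@interannualSd,
                   spatialNoiseSd = cfg@climate@spatialNoiseSd,
                   years = cfg@climate@years, seed = cfg@climate@seed),
    flammability = list(alpha = cfg@flammability@alpha,
                        beta = cfg@flammability@beta,
                        ignitionsPerYear = cfg@flammability@ignitionsPerYear,
                        minFireCells = cfg@flammability@minFireCells,
                        seed = cfg@flammability@seed),
    binWidth = cfg@binWidth, tau = cfg@tau, bootReps = cfg@bootReps,
    qrMaxPoints = cfg@qrMaxPoints, seed = cfg@seed, epochs = cfg@epochs, bands = cfg@bands,
    thresholds = cfg@thresholds, outDir = cfg@outDir, paths = cfg@paths)
  yaml::write_yaml(y, path)
  invisible(path)
}
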