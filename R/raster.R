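#' Construct a RasterGrid
#'
#' @param layers named list of numeric matrices (rows north to south).
#' @param xmin western edge, decimal degrees.
#' @param ymax northern edge, decimal degrees.
#' @param res cell size, decimal degrees.
#' @param mask optional logical matrix, `TRUE` = valid cell. Defaults to
#'   cells that are non-`NA` in every layer. `NA` is forced onto masked
#'   cells of every layer so the mask is shared exactly.
#' @return a [RasterGrid-class] object.
#' @export
RasterGrid <- function(layers, xmin = -180, ymax = 90, res = 1, mask = NULL) {
  stopifnot(is.list(layers), length(layers) > 0L)
  layers <- lapply(layers, function(l) {
    storage.mode(l) <- "double"
    l
  })
  dims <- dim(layers[[1L]])
  for (nm in names(layers))
    if (!identical(dim(layers[[nm]]), dims))
      stop("layer '", nm, "' dimensions differ from the first layer")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  }
  layers <- lapply(layers, function(l) {
    l[!mask] <- NA_real_
    l
  })
  new("RasterGrid", layers = layers, xmin = xmin, ymax = ymax,
      res = res, mask = mask, crs = "EPSG:4326")
}

#' @describeIn RasterGrid names of the stacked layers
#' @param x a `RasterGrid`.
#' @export
layerNames <- function(x) names(x@layers)

#' Extract or replace a single layer matrix
#'
#' @param x a [RasterGrid-class].
#' @param name layer name.
#' @param value numeric matrix with the grid's dimensions.
#' @return the layer as a numeric matrix (masked cells `NA`).
#' @export
rasterLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
}

#' @rdname rasterLayer
#' @export
`rasterLayer<-` <- function(x, name, value) {
  stopifnot(identical(dim(value), dim(x@mask)))
  storage.mode(value) <- "double"
  value[!x@mask] <- NA_real_
  x@layers[[name]] <- value
  validObject(x)
  x
}

#' @rdname rasterLayer
#' @export
rasterMask <- function(x) x@mask

#' @rdname rasterLayer
#' @export
rasterRes <- function(x) x@res

#' Extent of a RasterGrid as c(xmin, xmax, ymin, ymax)
#' @param x a [RasterGrid-class].
#' @export
rasterExtent <- function(x) {
  d <- dim(x@mask)
  c(xmin = x@xmin, xmax = x@xmin + d[2L] * x@res,
    ymin = x@ymax - d[1L] * x@res, ymax = x@ymax)
}

setMethod("dim", "RasterGrid", function(x) dim(x@mask))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@mask)
  e <- rasterExtent(object)
  cat("RasterGrid:", d[1L], "x", d[2L], "cells at", object@res, "deg (",
      object@crs, ")\n")
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
  cat(sprintf("  valid cells: %d of %d\n", sum(object@mask), length(object@mask)))
})

#' Map lon/lat coordinates to grid row/column indices
#'
#' Uses the package-wide half-open, top-left-origin convention:
#' `col = floor((lon - xmin)/res) + 1`, `row = floor((ymax - lat)/res) + 1`,
#' so a point exactly on a cell's western or northern edge belongs to that
#' cell. Points outside the extent get `NA` indices.
#'
#' @param x a [RasterGrid-class].
#' @param lon,lat coordinate vectors (decimal degrees).
#' @return data.frame with columns `row`, `col` (NA when outside).
#' @export
lonLatToCell <- function(x, lon, lat) {
  d <- dim(x@mask)
  col <- floor((lon - x@xmin) / x@res) + 1L
  row <- floor((x@ymax - lat) / x@res) + 1L
  # northern edge of the grid itself is included in the top row
  row[lat == x@ymax] <- 1L
  bad <- col < 1L | col > d[2L] | row < 1L | row > d[1L]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates for every grid cell
#' @param x a [RasterGrid-class].
#' @return data.frame `row, col, lon, lat` in row-major (north to south) order.
#' @export
cellCenters <- function(x) {
  d <- dim(x@mask)
  row <- rep(seq_len(d[1L]), each = d[2L])
  col <- rep(seq_len(d[2L]), times = d[1L])
  data.frame(row = row, col = col,
             lon = x@xmin + (col - 0.5) * x@res,
             lat = x@ymax - (row - 0.5) * x@res)
}

#' Per-cell area in hectares on the authalic sphere
#'
#' Cell area between latitudes phi1 > phi2 spanning `res` degrees of
#' longitude is `R^2 * (sin(phi1) - sin(phi2)) * res * pi/180` with the
#' authalic Earth radius R = 6371.002 km (constant within a row, shrinking
#' with the cosine of latitude).
#'
#' @param x a [RasterGrid-class].
#' @return numeric matrix of cell areas (ha), masked cells included.
#' @export
cellAreaHa <- function(x) {
  R <- 6371.002 # authalic radius, km
  d <- dim(x@mask)
  lat_top <- x@ymax - (seq_len(d[1L]) - 1L) * x@res
  lat_bot <- lat_top - x@res
  band <- R^2 * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180)) *
    x@res * pi / 180            # km^2 per cell in each row
  matrix(band * 100, nrow = d[1L], ncol = d[2L]) # 1 km^2 = 100 ha
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Write one layer as an ESRI ASCII grid (.asc)
#'
#' Plain-text single-band georeferenced raster: a 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values north to south. Geographic (EPSG:4326) north-up grids
#' round-trip exactly through [readAsciiGrid()] for finite values; masked
#' cells are written as the nodata sentinel.
#'
#' @param x a [RasterGrid-class].
#' @param name layer to write.
#' @param file output path.
#' @param nodata sentinel value for masked cells.
#' @return `file`, invisibly.
#' @export
writeAsciiGrid <- function(x, name, file, nodata = -9999) {
  m <- rasterLayer(x, name)
  d <- dim(m)
  e <- rasterExtent(x)
  hdr <- c(
    sprintf("ncols %d", d[2L]),
    sprintf("nrows %d", d[1L]),
    sprintf("xllcorner %.10g", e[["xmin"]]),
    sprintf("yllcorner %.10g", e[["ymin"]]),
    sprintf("cellsize %.10g", x@res),
    sprintf("NODATA_value %g", nodata)
  )
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid()]
#'
#' @param file path to a .asc file.
#' @param name layer name for the resulting single-layer grid.
#' @return a [RasterGrid-class] with one layer.
#' @export
readAsciiGrid <- function(file, name = "layer") {
  lines <- readLines(file)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1L]][2L])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  stopifnot(length(body) == nrows)
  m <- do.call(rbind, lapply(body, function(r)
    as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1L]])))
  stopifnot(ncol(m) == ncols)
  m[m == nodata] <- NA_real_
  RasterGrid(stats::setNames(list(m), name),
             xmin = xll, ymax = yll + nrows * cs, res = cs)
}

#' Read several .asc files into one RasterGrid stack
#' @param files named character vector of paths; names become layer names.
#' @return a [RasterGrid-class]; the shared mask is the intersection of the
#'   per-file valid cells.
#' @export
readAsciiStack <- function(files) {
  stopifnot(length(files) >= 1L, !is.null(names(files)))
  grids <- lapply(files, readAsciiGrid)
  g1 <- grids[[1L]]
  layers <- lapply(grids, function(g) g@layers[[1L]])
  names(layers) <- names(files)
  for (g in grids[-1L]) {
    stopifnot(identical(dim(g@mask), dim(g1@mask)),
              isTRUE(all.equal(g@xmin, g1@xmin)),
              isTRUE(all.equal(g@ymax, g1@ymax)),
              isTRUE(all.equal(g@res, g1@res)))
  }
  RasterGrid(layers, xmin = g1@xmin, ymax = g1@ymax, res = g1@res)
}
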