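#' Single-band raster grid
#'
#' A minimal in-memory raster: one named 2-D grid of values with a square
#' cell size in kilometres and a nodata marker. Rows are counted from the
#' top (north-up), columns from the left; cells are addressed row-major,
#' 0-based, matching the grid-unit indexing used throughout the package.
#'
#' @param values numeric matrix (rows x cols), row 1 = northern edge.
#' @param name layer name, e.g. `"esv"` or `"cultivated_area"`.
#' @param res cell edge length in km (default 1).
#' @param nodata value marking missing cells (default -9999).
#' @return an object of class `esv_raster`.
#' @export
esv_raster <- function(values, name = "layer", res = 1, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have positive dimensions")
  structure(
    list(values = values, name = name, res = res, nodata = nodata),
    class = "esv_raster"
  )
}

#' @export
print.esv_raster <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf(
    "<esv_raster> '%s': %d x %d cells @ %g km, range [%g, %g]\n",
    x$name, nrow(x$values), ncol(x$values), x$res,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
dim.esv_raster <- function(x) dim(x$values)

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by GDAL, QGIS and terra. Values
#' are written at full double precision, rows north to south.
#'
#' @param raster an [esv_raster].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  stopifnot(inherits(raster, "esv_raster"))
  v <- raster$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.17g", raster$res * 1000),  # metres
    sprintf("NODATA_value %.17g", raster$nodata))
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file written by [write_asc] (or any ESRI ASCII grid).
#' @param name layer name to attach; defaults to the file stem.
#' @return an [esv_raster]; cell size is converted back to km.
#' @export
read_asc <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  v <- t(vapply(body,
                function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]),
                numeric(hdr$ncols)))
  dimnames(v) <- NULL
  esv_raster(v, name = name, res = hdr$cellsize / 1000,
             nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
}

#' Aggregate a raster into coarser blocks
#'
#' Groups cells into `block` x `block` windows and reduces each window with
#' `sum` (extensive variables: areas, ESV, allocated totals) or `mean`
#' (intensive variables: NDVI, light index). Partial blocks at the southern
#' and eastern edges aggregate whatever cells they contain, so `mode = "sum"`
#' conserves the global total exactly.
#'
#' @param raster an [esv_raster].
#' @param block positive integer block edge, in cells.
#' @param mode `"sum"` or `"mean"`.
#' @return an [esv_raster] on the coarser grid (`res` scaled by `block`).
#' @export
aggregate_raster <- function(raster, block, mode = c("sum", "mean")) {
  stopifnot(inherits(raster, "esv_raster"))
  mode <- match.arg(mode)
  block <- as.integer(block)
  if (block < 1L) stop("`block` must be >= 1")
  v <- raster$values
  if (length(v) == 0L) stop("empty raster")
  if (block == 1L && mode == "sum") return(raster)
  ri <- (seq_len(nrow(v)) - 1L) %/% block
  ci <- (seq_len(ncol(v)) - 1L) %/% block
  f <- if (mode == "sum") sum else mean
  out <- matrix(NA_real_, max(ri) + 1L, max(ci) + 1L)
  for (r in unique(ri)) {
    rows <- which(ri == r)
    for (cc in unique(ci)) {
      out[r + 1L, cc + 1L] <- f(v[rows, which(ci == cc)])
    }
  }
  esv_raster(out, name = raster$name, res = raster$res * block,
             nodata = raster$nodata)
}

#' Convert a land-use area raster to percentages of the cell area
#'
#' @param area an [esv_raster] of per-cell class areas (same units as
#'   `cell_area`).
#' @param cell_area area of one cell; defaults to `res^2` (km^2).
#' @param tol tolerance for areas slightly exceeding the cell area.
#' @return an [esv_raster] with values in `[0, 100]`.
#' @export
landuse_percent <- function(area, cell_area = NULL, tol = 1e-8) {
  stopifnot(inherits(area, "esv_raster"))
  if (is.null(cell_area)) cell_area <- area$res^2
  v <- area$values
  if (any(v < -tol) || any(v > cell_area * (1 + tol)))
    stop("areas must lie within [0, cell_area]")
  v <- pmin(pmax(v, 0), cell_area)
  esv_raster(100 * v / cell_area, name = paste0(area$name, "_pct"),
             res = area$res, nodata = area$nodata)
}

#' Flatten a raster to the row-major grid-unit vector
#'
#' @param raster an [esv_raster].
#' @return numeric vector, units ordered row-major from the top-left cell.
#' @export
raster_units <- function(raster) {
  as.vector(t(raster$values))
}
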