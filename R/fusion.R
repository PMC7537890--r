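#' The 23 socioeconomic factor codes
#'
#' Growth quality A1-A8 (GDP, population, light index, 1st/2nd/3rd industry,
#' construction industry and tourism output), ecological protection B1-B7
#' (NDVI and the six land-use classes as area percentages), resource
#' utilization C1-C8 (total/agricultural/industrial/residential electricity
#' and water consumption).
#'
#' @return character vector of length 23.
#' @export
esv_factor_codes <- function() {
  c(paste0("A", 1:8), paste0("B", 1:7), paste0("C", 1:8))
}

#' Human-readable factor names, keyed by code
#' @return named character vector.
#' @export
esv_factor_names <- function() {
  c(A1 = "GDP", A2 = "Population", A3 = "Light index",
    A4 = "1st industry output value", A5 = "2nd industry output value",
    A6 = "3rd industry output value", A7 = "Construction industry output value",
    A8 = "Tourism output value",
    B1 = "NDVI", B2 = "Cultivated area", B3 = "Woodland area",
    B4 = "Grassland area", B5 = "Water area", B6 = "Construction land area",
    B7 = "Unused land area",
    C1 = "Electrical consumption", C2 = "Agricultural electricity consumption",
    C3 = "Industrial electricity consumption",
    C4 = "Residential electricity consumption",
    C5 = "Water consumption", C6 = "Agricultural water consumption",
    C7 = "Industrial water consumption", C8 = "Residential water consumption")
}

#' Default allocation spec: statistical indicators and weighting layers
#'
#' The 13 city-level statistical indicators that are spread over the grid by
#' dasymetric allocation, each paired with the ancillary raster that carries
#' its spatial weight: industry outputs follow the land-use class that hosts
#' the industry, tourism follows the nighttime light index, and electricity /
#' water consumption follow population or the matching land-use class.
#'
#' @return data.frame with columns `code` and `weighting_layer`.
#' @export
default_allocation_spec <- function() {
  data.frame(
    code = c("A4", "A5", "A6", "A7", "A8",
             "C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8"),
    weighting_layer = c(
      "cultivated_area",   # 1st industry output
      "industrial_area",   # 2nd industry output
      "residential_area",  # 3rd industry output
      "construction_area", # construction industry output
      "light_index",       # tourism output
      "population",        # electrical consumption
      "cultivated_area",   # agricultural electricity
      "industrial_area",   # industrial electricity
      "residential_area",  # residential electricity
      "population",        # water consumption
      "cultivated_area",   # agricultural water
      "industrial_area",   # industrial water
      "residential_area"), # residential water
    stringsAsFactors = FALSE)
}

#' Dasymetric allocation of a city total over a weighting raster
#'
#' Each grid unit receives `total * w_u / sum(w)`: the unit's share of the
#' ancillary weighting layer times the city-wide total, so the allocated
#' layer conserves the total exactly.
#'
#' @param total city-wide total of the indicator.
#' @param weights an [esv_raster] of non-negative weights, not all zero.
#' @param name name for the output layer.
#' @return an [esv_raster] of allocated values.
#' @export
allocate <- function(total, weights, name = "allocated") {
  stopifnot(inherits(weights, "esv_raster"))
  w <- weights$values
  if (any(w < 0)) stop("weighting layer contains negative values")
  ws <- sum(w)
  if (ws <= 0) stop("cannot allocate: weighting layer sums to zero")
  esv_raster(total * w / ws, name = name, res = weights$res,
             nodata = weights$nodata)
}

#' Construct a standardized sample table
#'
#' Z-standardizes every factor column and the response, storing the per-column
#' means and standard deviations (population SD, denominator n) so values can
#' be mapped back to original units. Constant columns abort: a factor with no
#' variance cannot be standardized nor swept.
#'
#' @param X numeric matrix, n units x factors, with column names.
#' @param Y numeric response vector (ESV per unit, original units).
#' @param landuse_cols codes of columns held on the 0-100 percent scale
#'   before standardization (land-use area proportions).
#' @param unit_ids optional unit identifiers.
#' @param standardize_landuse if `FALSE`, land-use percentage columns are
#'   passed through on the 0-100 scale instead of being z-scored.
#' @return an object of class `sample_table` with elements `X` (standardized
#'   matrix), `Y` (standardized response), `center`/`scale` (named, response
#'   stored under `"Y"`), `landuse_cols`, `unit_ids`.
#' @export
sample_table <- function(X, Y, landuse_cols = character(),
                         unit_ids = NULL, standardize_landuse = TRUE) {
  if (!is.matrix(X) || is.null(colnames(X)))
    stop("X must be a matrix with column names")
  if (nrow(X) != length(Y)) stop("X and Y disagree on sample count")
  if (anyNA(X) || anyNA(Y)) stop("missing values in sample table inputs")
  n <- nrow(X)
  pop_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  center <- colMeans(X)
  scale <- apply(X, 2L, pop_sd)
  if (any(scale == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[scale == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  skip <- intersect(landuse_cols, colnames(X))
  if (!standardize_landuse && length(skip)) {
    Z[, skip] <- X[, skip]
    center[skip] <- 0
    scale[skip] <- 1
  }
  ym <- mean(Y); ys <- pop_sd(Y)
  if (ys == 0) stop("constant response: cannot standardize ESV")
  structure(
    list(X = Z, Y = (Y - ym) / ys,
         center = c(center, Y = ym), scale = c(scale, Y = ys),
         landuse_cols = landuse_cols,
         unit_ids = if (is.null(unit_ids)) seq_len(n) - 1L else unit_ids),
    class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d units x %d factors (+ ESV response)\n",
              nrow(x$X), ncol(x$X)))
  cat(" land-use percentage columns:",
      if (length(x$landuse_cols)) paste(x$landuse_cols, collapse = " ")
      else "none", "\n")
  invisible(x)
}

#' Map standardized values back to original units
#'
#' @param table a [sample_table].
#' @param column factor code, or `"Y"` for the ESV response.
#' @param z standardized values.
#' @return values in original units.
#' @export
destandardize <- function(table, column, z) {
  stopifnot(inherits(table, "sample_table"))
  if (!column %in% names(table$center)) stop("unknown column: ", column)
  z * table$scale[[column]] + table$center[[column]]
}

#' Map original-unit values to the table's standardized scale
#'
#' @inheritParams destandardize
#' @param x values in original units.
#' @export
standardize_to <- function(table, column, x) {
  stopifnot(inherits(table, "sample_table"))
  if (!column %in% names(table$center)) stop("unknown column: ", column)
  (x - table$center[[column]]) / table$scale[[column]]
}

#' Fuse rasters and statistical totals into the analysis sample table
#'
#' Runs the preprocessing chain: aggregate every 1 km raster onto the
#' `block` x `block` km analysis grid (`sum` for extensive layers, `mean` for
#' NDVI and light index), allocate each statistical indicator over its
#' weighting layer, convert land-use areas to percentages of the unit area,
#' and z-standardize all 23 factor columns plus the ESV response.
#'
#' @param rasters named list of [esv_raster]s as produced by
#'   [generate_landscape]: `esv`, `gdp`, `population`, `light_index`, `ndvi`,
#'   one `<class>_area` per land-use class and the `industrial_area` /
#'   `residential_area` split of construction land.
#' @param totals named numeric vector of city totals for codes A4-A8, C1-C8.
#' @param spec allocation pairing table, defaults to
#'   [default_allocation_spec()].
#' @param block aggregation factor from the raster grid to analysis units
#'   (default 2: 1 km cells to 2 x 2 km units).
#' @param standardize_landuse passed to [sample_table].
#' @return a [sample_table] with 23 predictors and the ESV response.
#' @export
build_sample_table <- function(rasters, totals,
                               spec = default_allocation_spec(),
                               block = 2L, standardize_landuse = TRUE) {
  needed <- c("esv", "gdp", "population", "light_index", "ndvi",
              "cultivated_area", "woodland_area", "grassland_area",
              "water_area", "construction_area", "unused_area",
              "industrial_area", "residential_area")
  missing <- setdiff(needed, names(rasters))
  if (length(missing))
    stop("missing raster layer(s): ", paste(missing, collapse = ", "))
  if (!all(spec$code %in% names(totals)))
    stop("missing city total(s): ",
         paste(setdiff(spec$code, names(totals)), collapse = ", "))
  if (!all(spec$weighting_layer %in% names(rasters)))
    stop("allocation spec names unknown weighting layer(s): ",
         paste(setdiff(spec$weighting_layer, names(rasters)), collapse = ", "))

  agg <- function(nm, mode) aggregate_raster(rasters[[nm]], block, mode)
  cols <- list()
  cols[["A1"]] <- raster_units(agg("gdp", "sum"))
  cols[["A2"]] <- raster_units(agg("population", "sum"))
  cols[["A3"]] <- raster_units(agg("light_index", "mean"))
  # allocation happens on the analysis grid; Eq-style proportionality makes
  # this identical to allocating at 1 km and block-summing
  for (i in seq_len(nrow(spec))) {
    code <- spec$code[i]
    w <- agg(spec$weighting_layer[i], "sum")
    if (spec$weighting_layer[i] == "light_index")
      w <- agg("light_index", "mean")
    cols[[code]] <- raster_units(allocate(totals[[code]], w, name = code))
  }
  cols[["B1"]] <- raster_units(agg("ndvi", "mean"))
  lu <- c(B2 = "cultivated_area", B3 = "woodland_area", B4 = "grassland_area",
          B5 = "water_area", B6 = "construction_area", B7 = "unused_area")
  cell_area <- (rasters$esv$res * block)^2
  for (code in names(lu))
    cols[[code]] <- raster_units(landuse_percent(agg(lu[[code]], "sum"),
                                                 cell_area))
  codes <- esv_factor_codes()
  X <- do.call(cbind, cols[codes])
  colnames(X) <- codes
  Y <- raster_units(agg("esv", "sum"))
  sample_table(X, Y, landuse_cols = names(lu),
               standardize_landuse = standardize_landuse)
}

#' Write a sample table as CSV plus a JSON sidecar
#'
#' The CSV holds unit ids, the 23 standardized factors and standardized ESV;
#' the sidecar records the standardization parameters and land-use flags
#' needed to reconstruct original units.
#'
#' @param table a [sample_table].
#' @param path CSV path; the sidecar is written at `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(unit = table$unit_ids, table$X, Y = table$Y,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(center = as.list(table$center), scale = as.list(table$scale),
         landuse_cols = table$landuse_cols),
    paste0(path, ".params.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sample table written by [write_sample_table]
#' @param path CSV path with its `.params.json` sidecar alongside.
#' @return a [sample_table].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pr <- jsonlite::read_json(paste0(path, ".params.json"), simplifyVector = TRUE)
  codes <- setdiff(colnames(df), c("unit", "Y"))
  obj <- list(X = as.matrix(df[, codes, drop = FALSE]), Y = df$Y,
              center = unlist(pr$center), scale = unlist(pr$scale),
              landuse_cols = as.character(unlist(pr$landuse_cols)),
              unit_ids = df$unit)
  class(obj) <- "sample_table"
  obj
}
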