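#' Configuration for the synthetic city landscape
#'
#' Defines the study conditions the generator emulates: a rectangular 1 km
#' raster grid whose per-cell land-use composition, population, GDP,
#' nighttime light and NDVI surfaces are spatially autocorrelated random
#' fields, plus city-level statistical totals to be spread over the grid by
#' dasymetric allocation. Ground-truth ESV is the equivalent-factor
#' expansion: per-class area times a per-class value density, plus optional
#' Gaussian noise.
#'
#' Default value densities follow the qualitative ranking water > woodland >
#' grassland > cultivated > unused > construction; magnitudes are synthetic
#' stand-ins, never calibrated to any published coefficient table.
#'
#' @param grid_shape integer (rows, cols) in 1 km cells. The 64 x 64 default
#'   yields 1024 analysis units after 2 km aggregation, the same order as a
#'   mid-sized city.
#' @param seed integer seed governing every random field.
#' @param spatial_corr_length Gaussian smoothing length in km controlling
#'   landscape patchiness.
#' @param esv_coefficients named non-negative value densities (currency per
#'   km^2) for classes cultivated, woodland, grassland, water, construction,
#'   unused.
#' @param noise_sd ESV noise, as a fraction of the SD of the noise-free ESV
#'   signal across cells.
#' @param city_totals named totals for the statistical indicators A4-A8 and
#'   C1-C8 (industry outputs, electricity and water consumption).
#' @param population_total,gdp_total city totals the population and GDP
#'   rasters sum to exactly.
#' @param res cell edge length in km.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(64L, 64L),
                         seed = 1L,
                         spatial_corr_length = 6,
                         esv_coefficients = c(cultivated = 50, woodland = 180,
                                              grassland = 90, water = 300,
                                              construction = 5, unused = 20),
                         noise_sd = 0.1,
                         city_totals = c(A4 = 10000, A5 = 2e6, A6 = 5e5,
                                         A7 = 5e4, A8 = 2.5e4,
                                         C1 = 2.5e5, C2 = 100, C3 = 3e5,
                                         C4 = 6000, C5 = 2e4, C6 = 800,
                                         C7 = 1.2e4, C8 = 6000),
                         population_total = 8e6,
                         gdp_total = 1e7,
                         res = 1) {
  classes <- c("cultivated", "woodland", "grassland", "water",
               "construction", "unused")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers")
  if (!all(classes %in% names(esv_coefficients)))
    stop("esv_coefficients missing class(es): ",
         paste(setdiff(classes, names(esv_coefficients)), collapse = ", "))
  if (any(esv_coefficients < 0)) stop("esv_coefficients must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  need <- c(paste0("A", 4:8), paste0("C", 1:8))
  if (!all(need %in% names(city_totals)))
    stop("city_totals missing indicator(s): ",
         paste(setdiff(need, names(city_totals)), collapse = ", "))
  structure(list(grid_shape = grid_shape, seed = as.integer(seed),
                 spatial_corr_length = spatial_corr_length,
                 esv_coefficients = esv_coefficients[classes],
                 noise_sd = noise_sd, city_totals = city_totals,
                 population_total = population_total, gdp_total = gdp_total,
                 res = res, classes = classes),
            class = "synth_config")
}

# Smooth an iid N(0,1) matrix with a separable Gaussian kernel (reflecting
# edges), then rescale to zero mean / unit SD. sigma is in cells.
smooth_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    conv1 <- function(m) {
      # reflect-pad rows, convolve columns of m
      idx <- c(pmin(half:1, nrow(m)), seq_len(nrow(m)),
               pmax(nrow(m) - (1:half) + 1L, 1L))
      padded <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k))
        out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
      out
    }
    z <- conv1(z)        # smooth along rows
    z <- t(conv1(t(z)))  # smooth along cols
  }
  (z - mean(z)) / stats::sd(as.vector(z))
}

#' Generate a synthetic city: rasters and statistical totals
#'
#' Produces one raster per layer of the data model — ESV, GDP, population,
#' light index, NDVI, the six land-use class areas and the industrial /
#' residential split of construction land — plus the table of city-level
#' statistical totals. Land-use fractions come from a softmax over smoothed
#' Gaussian fields, so per-cell areas close exactly to the cell area; the
#' ESV raster is the per-class coefficient expansion plus seeded noise.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a [synth_config].
#' @return list with `rasters` (named list of [esv_raster]) and `totals`
#'   (named numeric: A4-A8, C1-C8 statistical totals plus the realized A1
#'   GDP and A2 population raster totals).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  sigma <- config$spatial_corr_length / config$res
  cell_area <- config$res^2
  withr::with_seed(config$seed, {
    # land-use mixture: one smoothed field per class, softmax-sharpened
    g <- lapply(config$classes, function(cl) smooth_field(nr, nc, sigma))
    names(g) <- config$classes
    ex <- lapply(g, function(m) exp(2 * m))
    denom <- Reduce(`+`, ex)
    frac <- lapply(ex, function(m) m / denom)

    split_f <- stats::plogis(1.5 * smooth_field(nr, nc, sigma))
    ind_area <- frac$construction * split_f * cell_area
    res_area <- frac$construction * (1 - split_f) * cell_area

    urban <- frac$construction
    pop_w <- exp(0.8 * smooth_field(nr, nc, sigma) + 2.5 * urban)
    pop <- config$population_total * pop_w / sum(pop_w)
    gdp_w <- exp(0.8 * smooth_field(nr, nc, sigma) + 2 * urban)
    gdp <- config$gdp_total * gdp_w / sum(gdp_w)
    light <- 600 * stats::plogis(0.8 * smooth_field(nr, nc, sigma) +
                                   3 * (urban - mean(urban)))
    veg <- frac$cultivated + frac$woodland + frac$grassland
    ndvi <- pmin(pmax(0.05 + 0.85 * veg +
                        0.05 * smooth_field(nr, nc, sigma), 0), 1)

    esv_signal <- Reduce(`+`, Map(function(f, coef) coef * f * cell_area,
                                  frac, config$esv_coefficients))
    noise <- if (config$noise_sd > 0)
      config$noise_sd * stats::sd(as.vector(esv_signal)) *
        matrix(stats::rnorm(nr * nc), nr, nc)
    else 0
    esv <- esv_signal + noise

    mk <- function(v, nm) esv_raster(v, name = nm, res = config$res)
    rasters <- c(
      list(esv = mk(esv, "esv"), gdp = mk(gdp, "gdp"),
           population = mk(pop, "population"),
           light_index = mk(light, "light_index"), ndvi = mk(ndvi, "ndvi")),
      stats::setNames(
        lapply(config$classes,
               function(cl) mk(frac[[cl]] * cell_area, paste0(cl, "_area"))),
        paste0(config$classes, "_area")),
      list(industrial_area = mk(ind_area, "industrial_area"),
           residential_area = mk(res_area, "residential_area")))
    totals <- c(config$city_totals,
                A1 = sum(gdp), A2 = sum(pop))
    list(rasters = rasters, totals = totals)
  })
}

#' Specification of a closed-form oracle table
#'
#' Ground truth for recovery tests: each factor can carry a planted effect of
#' a known shape — `monotone_increasing` / `monotone_decreasing` (linear with
#' slope `amplitude`), `u_shaped` / `inverted_u` (quadratic `amplitude *
#' (x - vertex)^2` with the stated sign), or `null` — so the response is
#' `Y = sum_i f_i(X_i) + noise`.
#'
#' @param n sample count.
#' @param effects named list, one entry per non-null factor code:
#'   `list(shape =, amplitude =, vertex = 0)`. Unlisted factors are null.
#' @param correlation equicorrelation level among factors, in `[0, 1)`.
#' @param noise_sd SD of the additive Gaussian noise on Y.
#' @param factors factor codes; defaults to the full 23-code set.
#' @return an object of class `oracle_spec`.
#' @export
oracle_spec <- function(n, effects, correlation = 0, noise_sd = 0,
                        factors = esv_factor_codes()) {
  shapes <- c("monotone_increasing", "monotone_decreasing",
              "u_shaped", "inverted_u")
  if (!length(effects)) stop("at least one non-null effect is required")
  if (is.null(names(effects)) || !all(names(effects) %in% factors))
    stop("effects must be named by factor code")
  for (e in effects) {
    if (!e$shape %in% shapes) stop("unknown shape: ", e$shape)
    if (e$amplitude < 0) stop("amplitudes must be >= 0")
  }
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n = as.integer(n), effects = effects,
                 correlation = correlation, noise_sd = noise_sd,
                 factors = factors),
            class = "oracle_spec")
}

oracle_effect_fun <- function(effect) {
  v <- if (is.null(effect$vertex)) 0 else effect$vertex
  a <- effect$amplitude
  switch(effect$shape,
         monotone_increasing = function(x) a * x,
         monotone_decreasing = function(x) -a * x,
         u_shaped = function(x) a * (x - v)^2,
         inverted_u = function(x) -a * (x - v)^2)
}

#' Generate an oracle table with a machine-readable truth record
#'
#' Factors are equicorrelated standard normals; the response adds the planted
#' per-factor effects and Gaussian noise, then everything is z-standardized
#' into a [sample_table]. The returned `truth` lists, for each factor, the
#' planted shape, amplitude and vertex, so recovery tests need no
#' re-derivation.
#'
#' @param spec an [oracle_spec].
#' @param seed integer seed.
#' @return list with `table` (a [sample_table]) and `truth` (data.frame:
#'   factor, shape, amplitude, vertex).
#' @export
generate_oracle_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "oracle_spec"))
  p <- length(spec$factors)
  withr::with_seed(as.integer(seed), {
    z0 <- stats::rnorm(spec$n)
    X <- sqrt(spec$correlation) * matrix(z0, spec$n, p) +
      sqrt(1 - spec$correlation) * matrix(stats::rnorm(spec$n * p), spec$n, p)
    colnames(X) <- spec$factors
    Y <- rep(0, spec$n)
    for (code in names(spec$effects))
      Y <- Y + oracle_effect_fun(spec$effects[[code]])(X[, code])
    if (spec$noise_sd > 0)
      Y <- Y + spec$noise_sd * stats::rnorm(spec$n)
  })
  truth <- data.frame(
    factor = spec$factors,
    shape = vapply(spec$factors, function(code) {
      if (code %in% names(spec$effects)) spec$effects[[code]]$shape
      else "null"
    }, character(1)),
    amplitude = vapply(spec$factors, function(code) {
      if (code %in% names(spec$effects)) spec$effects[[code]]$amplitude else 0
    }, numeric(1)),
    vertex = vapply(spec$factors, function(code) {
      e <- spec$effects[[code]]
      if (is.null(e) || is.null(e$vertex)) 0 else e$vertex
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = sample_table(X, Y), truth = truth)
}
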