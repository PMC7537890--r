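#' Configuration for response-curve analysis
#'
#' @param es_threshold range of the response domain at or above which a
#'   factor's influence intensity is "extremely significant" (ES).
#' @param s_threshold range at or above which (but below `es_threshold`)
#'   the intensity is "significant" (S); below it, "non-significant" (NS).
#' @param sweep_points points per single-factor sweep.
#' @param window odd centred moving-average window used to smooth curves
#'   before shape classification.
#' @param flat_tol differences smaller than this fraction of the curve
#'   amplitude are treated as flat when classifying shape.
#' @param pair_points points per axis of a two-factor coupling surface.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(es_threshold = 0.2, s_threshold = 0.1,
                            sweep_points = 201L, window = 5L,
                            flat_tol = 0.02, pair_points = 51L) {
  if (!(0 < s_threshold && s_threshold < es_threshold))
    stop("need 0 < s_threshold < es_threshold")
  if (sweep_points < 11L) stop("sweep_points must be >= 11")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  structure(list(es_threshold = es_threshold, s_threshold = s_threshold,
                 sweep_points = as.integer(sweep_points),
                 window = as.integer(window), flat_tol = flat_tol,
                 pair_points = as.integer(pair_points)),
            class = "analysis_config")
}

# Build the model-input row of sample means and the sweep grid for `factor`.
# Land-use percentage columns sweep on the 0-100 percent scale (converted to
# the model's standardized scale before prediction); all other factors sweep
# on the standardized scale over the observed range unless overridden.
sweep_grid <- function(table, factor, config, domain = NULL,
                       n_points = config$sweep_points) {
  if (!factor %in% colnames(table$X)) stop("unknown factor: ", factor)
  is_lu <- factor %in% table$landuse_cols
  if (is.null(domain)) {
    domain <- if (is_lu) {
      c(0, 100)
    } else {
      range(table$X[, factor])
    }
  }
  if (diff(domain) <= 0) stop("degenerate sampling domain for ", factor)
  xs <- seq(domain[1], domain[2], length.out = n_points)
  xs_std <- if (is_lu) standardize_to(table, factor, xs) else xs
  list(xs = xs, xs_std = xs_std, domain = domain,
       scale = if (is_lu) "percent" else "standardized")
}

sweep_inputs <- function(table, factor, xs_std) {
  base <- colMeans(table$X)
  X <- matrix(base, length(xs_std), length(base), byrow = TRUE)
  colnames(X) <- colnames(table$X)
  X[, factor] <- xs_std
  X
}

#' Single-factor response curve
#'
#' Holds every other factor at its sample mean and sweeps the target factor
#' across its sampling domain; the traced interval of predicted ESV is the
#' response domain, whose width (`range`) measures the factor's influence
#' intensity, classified ES / S / NS against the config thresholds, and
#' whose trend is classified into the shape taxonomy by [classify_shape].
#'
#' @param model an `esv_mlp`.
#' @param table the [sample_table] the model was trained on.
#' @param factor one of the 23 factor codes.
#' @param config an [analysis_config].
#' @param domain optional sampling-domain override `c(lo, hi)` on the sweep
#'   scale (standardized; percent for land-use columns).
#' @return an object of class `response_curve`: `factor`, `sampling_domain`,
#'   `sweep_scale`, `xs`, `ys` (standardized ESV), `range`, `intensity`,
#'   `shape`.
#' @export
single_factor_response <- function(model, table, factor,
                                   config = analysis_config(),
                                   domain = NULL) {
  g <- sweep_grid(table, factor, config, domain)
  ys <- predict(model, sweep_inputs(table, factor, g$xs_std))
  rng <- max(ys) - min(ys)
  structure(
    list(factor = factor, sampling_domain = g$domain, sweep_scale = g$scale,
         xs = g$xs, ys = ys, range = rng,
         intensity = classify_intensity(rng, config),
         shape = classify_shape(g$xs, ys, config)),
    class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(
    "<response_curve> %s: domain (%g, %g) [%s], range %.4f (%s), %s\n",
    x$factor, x$sampling_domain[1], x$sampling_domain[2], x$sweep_scale,
    x$range, x$intensity, x$shape))
  invisible(x)
}

#' Classify influence intensity from a response-domain range
#'
#' ES when the range is at least the ES threshold, S when at least the S
#' threshold, NS otherwise (thresholds inclusive upward).
#'
#' @param range non-negative response-domain width.
#' @param config an [analysis_config].
#' @return `"ES"`, `"S"` or `"NS"`.
#' @export
classify_intensity <- function(range, config = analysis_config()) {
  if (range < 0) stop("range must be >= 0")
  if (range >= config$es_threshold) "ES"
  else if (range >= config$s_threshold) "S"
  else "NS"
}

smooth_curve <- function(ys, window) {
  if (window <= 1L) return(ys)
  half <- (window - 1L) %/% 2L
  n <- length(ys)
  padded <- c(rep(ys[1L], half), ys, rep(ys[n], half))
  stats::filter(padded, rep(1 / window, window), sides = 2L)[
    (half + 1L):(half + n)]
}

#' Classify the shape of a response curve
#'
#' Smooths the curve with a centred moving average, then collapses it into a
#' sequence of significant monotone segments: a direction only registers
#' once the curve has moved `flat_tol` of the overall amplitude in that
#' direction, and reverses only after an opposing excursion of the same
#' size, so movements smaller than the tolerance are flat. No direction
#' change gives a monotone label, a single `- -> +` change is U-shaped, a
#' single `+ -> -` change is inverted-U, and more than one change is
#' increasing / decreasing with fluctuation by the sign of the net change.
#' An entirely flat curve is labelled monotone with a `zero_range`
#' attribute rather than failing.
#'
#' @param xs,ys sweep coordinates (at least 11 points).
#' @param config an [analysis_config].
#' @return one of `"monotone_increasing"`, `"monotone_decreasing"`,
#'   `"u_shaped"`, `"inverted_u"`, `"increasing_with_fluctuation"`,
#'   `"decreasing_with_fluctuation"`.
#' @export
classify_shape <- function(xs, ys, config = analysis_config()) {
  if (length(ys) < 11L) stop("need at least 11 sweep points")
  sm <- smooth_curve(ys, config$window)
  amp <- max(sm) - min(sm)
  if (amp == 0)
    return(structure("monotone_increasing", zero_range = TRUE))
  dirs <- segment_directions(sm, config$flat_tol * amp)
  if (!length(dirs))
    return(structure("monotone_increasing", zero_range = TRUE))
  changes <- length(dirs) - 1L
  net_up <- sm[length(sm)] >= sm[1L]
  if (changes == 0L) {
    if (dirs[1L] > 0) "monotone_increasing" else "monotone_decreasing"
  } else if (changes == 1L) {
    if (dirs[1L] < 0) "u_shaped" else "inverted_u"
  } else {
    if (net_up) "increasing_with_fluctuation"
    else "decreasing_with_fluctuation"
  }
}

# Zigzag filter: directions of monotone segments whose excursion reaches
# `thr`; an empty result means the whole curve stays within the tolerance.
segment_directions <- function(sm, thr) {
  dirs <- integer(0)
  cur <- 0L
  ext <- sm[1L]  # running extreme in the current direction (or the anchor)
  for (v in sm[-1L]) {
    if (cur == 0L) {
      if (v >= ext + thr) { cur <- 1L; ext <- v }
      else if (v <= ext - thr) { cur <- -1L; ext <- v }
    } else if (cur == 1L) {
      if (v > ext) ext <- v
      else if (v <= ext - thr) { dirs <- c(dirs, 1L); cur <- -1L; ext <- v }
    } else {
      if (v < ext) ext <- v
      else if (v >= ext + thr) { dirs <- c(dirs, -1L); cur <- 1L; ext <- v }
    }
  }
  c(dirs, if (cur != 0L) cur)
}

#' Locate a curve's extremum in original units
#'
#' For U-shaped curves the minimum, for inverted-U curves the maximum, of
#' the smoothed sweep, mapped back to original factor and ESV units via the
#' table's stored standardization parameters. Monotone curves return the
#' endpoint attaining the extreme value, flagged `monotone = TRUE`.
#'
#' @param curve a [response_curve].
#' @param table the [sample_table] carrying standardization parameters.
#' @param config an [analysis_config] (smoothing window).
#' @return list with `x_star`, `y_star` (original units), `kind`
#'   (`"min"`/`"max"`) and `monotone` flag.
#' @export
find_extremum <- function(curve, table, config = analysis_config()) {
  stopifnot(inherits(curve, "response_curve"))
  if (!all(c(curve$factor, "Y") %in% names(table$center)))
    stop("table lacks standardization parameters for ", curve$factor)
  sm <- smooth_curve(curve$ys, config$window)
  monotone <- curve$shape %in% c("monotone_increasing", "monotone_decreasing")
  kind <- if (curve$shape == "u_shaped") "min"
          else if (curve$shape == "inverted_u") "max"
          else if (curve$shape %in%
                     c("monotone_increasing", "increasing_with_fluctuation"))
            "max"
          else "min"
  i <- if (kind == "min") which.min(sm) else which.max(sm)
  x_std <- curve$xs[i]
  x_orig <- if (curve$sweep_scale == "percent") x_std
            else destandardize(table, curve$factor, x_std)
  list(x_star = x_orig,
       y_star = destandardize(table, "Y", sm[i]),
       kind = kind, monotone = monotone)
}

#' Two-factor coupling surface
#'
#' Evaluates predicted ESV on the tensor grid of two factors' sampling
#' domains with the remaining 21 factors at their sample means, exposing
#' joint (interaction) effects and the factor combination maximizing ESV.
#'
#' @param model an `esv_mlp`.
#' @param table the training [sample_table].
#' @param f1,f2 distinct factor codes.
#' @param config an [analysis_config] (`pair_points` per axis).
#' @param domain1,domain2 optional per-factor domain overrides.
#' @return an object of class `coupling_surface`: `factors`, `x1`, `x2`
#'   (axis grids on sweep scale), `Z` (`pair_points` x `pair_points`
#'   predicted ESV, rows follow `x1`), `argmax` (data.frame of maximizing
#'   grid cells).
#' @export
pair_response_surface <- function(model, table, f1, f2,
                                  config = analysis_config(),
                                  domain1 = NULL, domain2 = NULL) {
  if (identical(f1, f2)) stop("factors must differ")
  g1 <- sweep_grid(table, f1, config, domain1, n_points = config$pair_points)
  g2 <- sweep_grid(table, f2, config, domain2, n_points = config$pair_points)
  base <- colMeans(table$X)
  n1 <- length(g1$xs); n2 <- length(g2$xs)
  X <- matrix(base, n1 * n2, length(base), byrow = TRUE)
  colnames(X) <- colnames(table$X)
  X[, f1] <- rep(g1$xs_std, times = n2)
  X[, f2] <- rep(g2$xs_std, each = n1)
  Z <- matrix(predict(model, X), n1, n2)
  best <- which(Z == max(Z), arr.ind = TRUE)
  structure(
    list(factors = c(f1, f2), x1 = g1$xs, x2 = g2$xs,
         scales = c(g1$scale, g2$scale), Z = Z,
         argmax = data.frame(x1 = g1$xs[best[, 1L]], x2 = g2$xs[best[, 2L]],
                             z = Z[best])),
    class = "coupling_surface")
}

#' @export
print.coupling_surface <- function(x, ...) {
  cat(sprintf("<coupling_surface> %s x %s (%d x %d), max ESV %.4f at (%g, %g)\n",
              x$factors[1], x$factors[2], nrow(x$Z), ncol(x$Z),
              x$argmax$z[1], x$argmax$x1[1], x$argmax$x2[1]))
  invisible(x)
}

#' Response report over all factors
#'
#' Sweeps every factor column and tabulates sampling domain, response-domain
#' range, influence intensity and function shape — the per-factor summary a
#' driver analysis reads off first.
#'
#' @param model an `esv_mlp`.
#' @param table the training [sample_table].
#' @param config an [analysis_config].
#' @param factors factor codes to include (default: all columns).
#' @return data.frame, one row per factor, sorted by decreasing range.
#' @export
response_report <- function(model, table, config = analysis_config(),
                            factors = colnames(table$X)) {
  curves <- lapply(factors, function(f)
    single_factor_response(model, table, f, config))
  out <- data.frame(
    factor = factors,
    domain_lo = vapply(curves, function(cv) cv$sampling_domain[1], numeric(1)),
    domain_hi = vapply(curves, function(cv) cv$sampling_domain[2], numeric(1)),
    sweep_scale = vapply(curves, `[[`, character(1), "sweep_scale"),
    range = vapply(curves, `[[`, numeric(1), "range"),
    intensity = vapply(curves, `[[`, character(1), "intensity"),
    shape = vapply(curves, function(cv) as.character(cv$shape), character(1)),
    stringsAsFactors = FALSE)
  out[order(-out$range), , drop = FALSE]
}
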