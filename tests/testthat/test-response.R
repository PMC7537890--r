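test_that("analysis_config enforces threshold ordering and window shape", {
  expect_error(analysis_config(es_threshold = 0.1, s_threshold = 0.2),
               "s_threshold")
  expect_error(analysis_config(sweep_points = 5), "sweep_points")
  expect_error(analysis_config(window = 4), "odd")
})

test_that("a constant model yields zero range and NS for every factor", {
  m <- constant_mlp(1.2)
  rep <- response_report(m, tiny_table)
  expect_true(all(rep$range == 0))
  expect_true(all(rep$intensity == "NS"))
})

test_that("planted effect strength orders the response ranges", {
  # quick_oracle plants a strong A1 slope and a strong B5 inverted-U;
  # everything else is null, so those two must dominate the ranges
  rep <- response_report(quick_model, quick_oracle$table)
  expect_setequal(rep$factor[1:2], c("A1", "B5"))
  cv <- single_factor_response(quick_model, quick_oracle$table, "A1")
  expect_equal(as.character(cv$shape), "monotone_increasing")
})

test_that("unknown factors and degenerate domains are rejected", {
  expect_error(single_factor_response(quick_model, quick_oracle$table, "Z1"),
               "unknown factor")
  expect_error(single_factor_response(quick_model, quick_oracle$table, "A1",
                                      domain = c(1, 1)), "degenerate")
})

test_that("intensity classes split on the 0.2 / 0.1 thresholds", {
  cfg <- analysis_config()
  # printed-range examples spanning the three classes
  expect_equal(classify_intensity(0.310, cfg), "ES")
  expect_equal(classify_intensity(0.181, cfg), "S")
  expect_equal(classify_intensity(0.094, cfg), "NS")
  # boundary convention: thresholds inclusive upward
  expect_equal(classify_intensity(0.2, cfg), "ES")
  expect_equal(classify_intensity(0.1, cfg), "S")
  expect_error(classify_intensity(-0.1, cfg), ">= 0")
})

test_that("intensity never demotes as the range grows", {
  cfg <- analysis_config()
  lv <- c(NS = 1, S = 2, ES = 3)
  ranges <- sort(c(runif(50, 0, 0.4), 0.1, 0.2))
  cls <- lv[vapply(ranges, classify_intensity, character(1), cfg)]
  expect_true(all(diff(cls) >= 0))
})

test_that("analytic curves are labelled by their construction", {
  xs <- seq(-3, 3, length.out = 201)
  cfg <- analysis_config()
  expect_equal(as.character(classify_shape(xs, xs, cfg)),
               "monotone_increasing")
  expect_equal(as.character(classify_shape(xs, -2 * xs, cfg)),
               "monotone_decreasing")
  expect_equal(as.character(classify_shape(xs, (xs - 0.5)^2, cfg)),
               "u_shaped")
  expect_equal(as.character(classify_shape(xs, -(xs + 1)^2, cfg)),
               "inverted_u")
  expect_equal(as.character(classify_shape(xs, xs + 0.3 * sin(6 * xs), cfg)),
               "increasing_with_fluctuation")
  expect_equal(as.character(classify_shape(xs, -xs + 0.3 * sin(6 * xs), cfg)),
               "decreasing_with_fluctuation")
  flat <- classify_shape(xs, rep(1, 201), cfg)
  expect_true(attr(flat, "zero_range"))
})

test_that("extrema destandardize through the stored parameters", {
  # curve with an inverted-U vertex at standardized 0.5 on a factor with
  # mean 10 kt and SD 4 kt: the peak sits at 12 kt in original units
  tab <- tiny_table
  tab$center[["C5"]] <- 10
  tab$scale[["C5"]] <- 4
  xs <- seq(-2, 2, length.out = 201)
  curve <- structure(
    list(factor = "C5", sampling_domain = range(xs),
         sweep_scale = "standardized", xs = xs, ys = -(xs - 0.5)^2,
         range = max(-(xs - 0.5)^2) - min(-(xs - 0.5)^2),
         intensity = "ES", shape = "inverted_u"),
    class = "response_curve")
  ex <- find_extremum(curve, tab)
  expect_equal(ex$kind, "max")
  expect_false(ex$monotone)
  expect_equal(ex$x_star, 12, tolerance = 0.05)
  # the smoothed peak value is ~0 on the standardized scale, so y_star
  # destandardizes to (about) the stored ESV mean
  expect_equal(ex$y_star, tab$center[["Y"]],
               tolerance = 1e-3 * abs(tab$scale[["Y"]]))
})

test_that("monotone curves return the attaining endpoint, flagged", {
  xs <- seq(-1, 1, length.out = 101)
  curve <- structure(
    list(factor = "A1", sampling_domain = c(-1, 1),
         sweep_scale = "standardized", xs = xs, ys = 2 * xs, range = 4,
         intensity = "ES", shape = "monotone_increasing"),
    class = "response_curve")
  ex <- find_extremum(curve, tiny_table)
  expect_true(ex$monotone)
  expect_equal(ex$x_star, destandardize(tiny_table, "A1", 1))
})

test_that("the planted inverted-U vertex is recovered on the oracle", {
  cv <- single_factor_response(quick_model, quick_oracle$table, "B5")
  expect_equal(as.character(cv$shape), "inverted_u")
  ex <- find_extremum(cv, quick_oracle$table)
  vertex_std <- standardize_to(quick_oracle$table, "B5", ex$x_star)
  width <- diff(cv$sampling_domain)
  truth <- quick_oracle$truth
  planted <- truth$vertex[truth$factor == "B5"]
  expect_lt(abs(vertex_std - planted), 0.1 * width)
})

test_that("an additive surrogate has a separable coupling surface", {
  m <- manual_mlp(list(
    list(w = c(A1 = 1), b = 2, out = 1),    # relu(x1 + 2) ~ linear in range
    list(w = c(A2 = -1), b = 2, out = 0.5)))
  surf <- pair_response_surface(m, tiny_table, "A1", "A2",
                                analysis_config(pair_points = 21))
  # rows differ by a column-constant: mixed second differences vanish
  rd <- diff(surf$Z)       # along x1
  dev <- apply(rd, 1, function(r) max(r) - min(r))
  expect_lt(max(dev), 1e-6)
})

test_that("an interacting surrogate peaks where its kink dictates", {
  # f = relu(-(x1 + x2)): maximal where x1 + x2 is smallest, i.e. the
  # bottom-left corner of the sweep rectangle
  m <- manual_mlp(list(list(w = c(A1 = -1, A2 = -1), b = 0, out = 1)))
  surf <- pair_response_surface(m, tiny_table, "A1", "A2",
                                analysis_config(pair_points = 21))
  expect_equal(surf$argmax$x1[1], min(surf$x1))
  expect_equal(surf$argmax$x2[1], min(surf$x2))
  expect_equal(max(surf$Z), surf$argmax$z[1])
})

test_that("a 1x1 pair grid degenerates to a point evaluation", {
  surf <- pair_response_surface(quick_model, quick_oracle$table, "A1", "A2",
                                analysis_config(pair_points = 11),
                                domain1 = c(0, 1e-9), domain2 = c(0, 1e-9))
  expect_error(pair_response_surface(quick_model, quick_oracle$table,
                                     "A1", "A1"), "differ")
  base <- colMeans(quick_oracle$table$X)
  X <- matrix(base, 1, length(base), byrow = TRUE,
              dimnames = list(NULL, names(base)))
  X[, "A1"] <- 0
  X[, "A2"] <- 0
  expect_equal(surf$Z[1, 1], predict(quick_model, X), tolerance = 1e-6)
})

test_that("sweep ranges are stable under 10x grid refinement", {
  for (f in c("A1", "B5")) {
    c1 <- single_factor_response(quick_model, quick_oracle$table, f,
                                 analysis_config(sweep_points = 201))
    c2 <- single_factor_response(quick_model, quick_oracle$table, f,
                                 analysis_config(sweep_points = 2001))
    expect_lt(abs(c1$range - c2$range), 0.02 * max(c2$range, 1e-12))
  }
})
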