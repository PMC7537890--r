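test_that("synth_config validates its invariants", {
  expect_error(synth_config(grid_shape = c(0, 4)), "positive")
  expect_error(synth_config(esv_coefficients = c(cultivated = 1)), "missing")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(city_totals = c(A4 = 1)), "missing")
})

test_that("the landscape generator is seed-deterministic", {
  a <- generate_landscape(synth_config(grid_shape = c(12, 12), seed = 5))
  b <- generate_landscape(synth_config(grid_shape = c(12, 12), seed = 5))
  d <- generate_landscape(synth_config(grid_shape = c(12, 12), seed = 6))
  expect_identical(a$rasters, b$rasters)
  expect_identical(a$totals, b$totals)
  expect_false(identical(a$rasters$esv$values, d$rasters$esv$values))
})

test_that("per-cell land-use fractions close to the cell area", {
  cfg <- tiny_config
  areas <- lapply(paste0(cfg$classes, "_area"),
                  function(nm) tiny_land$rasters[[nm]]$values)
  expect_lt(max(abs(Reduce(`+`, areas) - cfg$res^2)), 1e-9)
  # the industrial/residential split partitions construction land
  recon <- tiny_land$rasters$industrial_area$values +
    tiny_land$rasters$residential_area$values
  expect_equal(recon, tiny_land$rasters$construction_area$values,
               tolerance = 1e-12)
})

test_that("noise-free ESV equals the coefficient expansion exactly", {
  cfg <- synth_config(grid_shape = c(10, 10), seed = 3, noise_sd = 0)
  land <- generate_landscape(cfg)
  expansion <- Reduce(`+`, lapply(cfg$classes, function(cl)
    cfg$esv_coefficients[[cl]] * land$rasters[[paste0(cl, "_area")]]$values))
  expect_identical(land$rasters$esv$values, expansion)
  # a cell entirely of one class would contribute coefficient x area; the
  # expansion identity covers every mixture including that limit
})

test_that("population and GDP rasters sum to their city totals", {
  expect_equal(sum(tiny_land$rasters$population$values),
               tiny_land$totals[["A2"]], tolerance = 1e-6)
  expect_equal(sum(tiny_land$rasters$gdp$values),
               tiny_land$totals[["A1"]], tolerance = 1e-6)
})

test_that("oracle_spec validates shapes, amplitudes and correlation", {
  expect_error(oracle_spec(10, list()), "at least one")
  expect_error(oracle_spec(10, list(A1 = list(shape = "wiggly",
                                              amplitude = 1))), "shape")
  expect_error(oracle_spec(10, list(A1 = list(shape = "u_shaped",
                                              amplitude = -1))), "amplitude")
  expect_error(oracle_spec(10, list(A1 = list(shape = "u_shaped",
                                              amplitude = 1)),
                           correlation = 1), "correlation")
})

test_that("a noiseless single monotone effect is perfectly rank-correlated", {
  res <- generate_oracle_table(
    oracle_spec(200, list(A3 = list(shape = "monotone_increasing",
                                    amplitude = 2))),
    seed = 4)
  rho <- cor(res$table$X[, "A3"], res$table$Y, method = "spearman")
  expect_equal(rho, 1)
})

test_that("pure-noise responses decorrelate from every factor", {
  res <- generate_oracle_table(
    oracle_spec(10000, list(A1 = list(shape = "monotone_increasing",
                                      amplitude = 0)),
                noise_sd = 1),
    seed = 8)
  r <- abs(cor(res$table$X, res$table$Y))
  expect_lt(max(r), 3 / sqrt(10000))
})

test_that("a planted inverted-U lifts the middle tercile of the response", {
  res <- generate_oracle_table(
    oracle_spec(3000, list(B2 = list(shape = "inverted_u", amplitude = 1,
                                     vertex = 0))),
    seed = 12)
  x <- res$table$X[, "B2"]
  terc <- cut(x, quantile(x, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
              labels = c("lo", "mid", "hi"))
  means <- tapply(res$table$Y, terc, mean)
  expect_gt(means[["mid"]], means[["lo"]])
  expect_gt(means[["mid"]], means[["hi"]])
})

test_that("every oracle table ships a machine-readable truth record", {
  res <- quick_oracle
  expect_named(res$truth, c("factor", "shape", "amplitude", "vertex"))
  expect_setequal(res$truth$factor, esv_factor_codes())
  expect_equal(res$truth$shape[res$truth$factor == "B5"], "inverted_u")
  expect_equal(res$truth$amplitude[res$truth$factor == "A1"], 1)
  expect_true(all(res$truth$shape[!res$truth$factor %in% c("A1", "B5")] ==
                    "null"))
})

test_that("equicorrelated factors carry the requested correlation level", {
  res <- generate_oracle_table(
    oracle_spec(5000, list(A1 = list(shape = "monotone_increasing",
                                     amplitude = 1)),
                correlation = 0.4),
    seed = 31)
  cm <- cor(res$table$X)
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.4, tolerance = 0.05)
})
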