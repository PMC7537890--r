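# Shared fixtures, built once per test run.

# Small synthetic city for fusion/pipeline mechanics.
tiny_config <- synth_config(grid_shape = c(16L, 16L), seed = 42L,
                            spatial_corr_length = 3)
tiny_land <- generate_landscape(tiny_config)
tiny_table <- build_sample_table(tiny_land$rasters, tiny_land$totals)

# A quick trained surrogate on an oracle table with two strong planted
# effects; enough epochs to shape the response surface, cheap to fit.
quick_oracle <- generate_oracle_table(
  oracle_spec(400L, effects = list(
    A1 = list(shape = "monotone_increasing", amplitude = 1),
    B5 = list(shape = "inverted_u", amplitude = 0.8, vertex = 0.2)),
    noise_sd = 0.1),
  seed = 99L)
quick_model <- train_surrogate(quick_oracle$table,
                               mlp_config(epochs = 40L, seed = 7L))

# Hand-built network on the full 23-factor input: one hidden ReLU layer of
# width `length(units)` feeding a linear scalar output. `units` is a list of
# list(w = <23-vector or named>, b =, out =) describing each hidden unit.
manual_mlp <- function(units, bias_out = 0, factors = esv_factor_codes()) {
  p <- length(factors)
  W1 <- matrix(0, p, length(units))
  b1 <- numeric(length(units))
  w2 <- numeric(length(units))
  for (j in seq_along(units)) {
    u <- units[[j]]
    wv <- numeric(p)
    names(wv) <- factors
    wv[names(u$w)] <- u$w
    W1[, j] <- wv
    b1[j] <- if (is.null(u$b)) 0 else u$b
    w2[j] <- u$out
  }
  structure(list(W = list(W1, matrix(w2, ncol = 1L)),
                 b = list(b1, bias_out),
                 activations = c("relu", "linear"),
                 config = mlp_config(), feature_names = factors),
            class = "esv_mlp")
}

# A constant-output model: all weights zero, output bias `value`.
constant_mlp <- function(value = 0.5, factors = esv_factor_codes()) {
  manual_mlp(list(list(w = c(A1 = 0), b = 0, out = 0)),
             bias_out = value, factors = factors)
}
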