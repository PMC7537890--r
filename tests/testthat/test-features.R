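test_that("predictions decompose exactly through the penultimate layer", {
  withr::with_seed(17, {
    X <- matrix(rnorm(200 * 23), 200, 23,
                dimnames = list(NULL, esv_factor_codes()))
  })
  H <- penultimate_activations(quick_model, X)
  expect_true(all(H >= 0))  # ReLU layer
  ow <- output_weights(quick_model)
  recon <- as.vector(H %*% ow$w + ow$b)
  expect_lt(max(abs(recon - predict(quick_model, X))), 1e-6)
})

test_that("zeroing one output weight shifts predictions by -w_j h_j", {
  withr::with_seed(18, {
    X <- matrix(rnorm(50 * 23), 50, 23,
                dimnames = list(NULL, esv_factor_codes()))
  })
  H <- penultimate_activations(quick_model, X)
  ow <- output_weights(quick_model)
  j <- which.max(abs(ow$w))
  clipped <- quick_model
  clipped$W[[length(clipped$W)]][j, 1] <- 0
  delta <- predict(clipped, X) - predict(quick_model, X)
  expect_equal(delta, -ow$w[j] * H[, j], tolerance = 1e-9)
})

test_that("feature extraction requires a linear scalar output", {
  m <- quick_model
  m$activations[length(m$activations)] <- "relu"
  expect_error(penultimate_activations(m, quick_oracle$table$X), "linear")
})

test_that("a single-neuron model matches its closed-form contribution", {
  cc <- 0.7
  m <- manual_mlp(list(list(w = c(A1 = 1), b = 0, out = cc)))
  tab <- quick_oracle$table
  feats <- extract_features(m, tab, feature_config(theta_contrib = 1e-9))
  # h1 = relu(x1): its sweep range over the observed domain is relu(max)
  dom <- range(tab$X[, "A1"])
  expected <- cc * (max(dom, 0) - max(min(dom), 0))
  ft <- feats$features[[1]]
  expect_equal(unname(ft$contributions[["A1"]]), expected, tolerance = 1e-9)
  expect_true("A1" %in% ft$contained)
  # null factors drive the neuron not at all
  expect_lt(max(ft$contributions[setdiff(names(ft$contributions), "A1")]),
            1e-12)
})

test_that("containment thresholds at theta_contrib", {
  contributions <- c(A1 = 0.000964, A2 = 0.001185, A3 = 0.0001)
  contained <- names(contributions)[contributions >= 3e-4]
  expect_setequal(contained, c("A1", "A2"))
  # and through the extractor: everything below threshold is excluded
  m <- manual_mlp(list(list(w = c(A1 = 1e-4), b = 0, out = 1e-4)))
  feats <- extract_features(m, quick_oracle$table, feature_config())
  expect_equal(length(feats$features), 0L)
})

test_that("zero-weight neurons are excluded as dead features", {
  m <- manual_mlp(list(list(w = c(A1 = 1), b = 0, out = 1),
                       list(w = c(A2 = 1), b = 0, out = 0)))
  feats <- extract_features(m, quick_oracle$table,
                            feature_config(theta_contrib = 1e-9))
  expect_equal(vapply(feats$features, `[[`, integer(1), "neuron"), 1L)
})

test_that("features are ranked by weight and capped at the layer width", {
  feats <- extract_features(quick_model, quick_oracle$table,
                            feature_config())
  expect_lte(length(feats$features), 16L)
  w <- vapply(feats$features, `[[`, numeric(1), "weight")
  expect_true(all(diff(w) <= 0))
  for (ft in feats$features) {
    expect_true(all(ft$contained %in% esv_factor_codes()))
    expect_setequal(ft$contained,
                    names(ft$contributions)[ft$contributions >= 3e-4])
  }
})

test_that("feature contributions are stable under 10x sweep refinement", {
  f1 <- extract_features(quick_model, quick_oracle$table,
                         feature_config(sweep_points = 201))
  f2 <- extract_features(quick_model, quick_oracle$table,
                         feature_config(sweep_points = 2001))
  amp <- max(f2$contributions)
  expect_lt(max(abs(f1$contributions - f2$contributions)), 0.02 * amp)
})

test_that("PCA loadings are orthonormal with non-increasing variance", {
  pca <- pca_compare(tiny_table, n_components = 6)
  G <- crossprod(pca$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-8)
  expect_true(all(diff(pca$explained) <= 1e-12))
})

test_that("independent factors give near-uniform explained variance", {
  withr::with_seed(23, {
    X <- matrix(rnorm(10000 * 23), 10000, 23,
                dimnames = list(NULL, esv_factor_codes()))
  })
  tab <- sample_table(X, rnorm(10000))
  pca <- pca_compare(tab, n_components = 23)
  expect_lt(max(pca$explained) / min(pca$explained), 1.5)
})

test_that("a duplicated column pair loads PC1 equally", {
  withr::with_seed(24, {
    z <- rnorm(500)
    X <- cbind(A1 = z, A2 = z + rnorm(500, sd = 1e-8),
               A3 = rnorm(500), A4 = rnorm(500))
  })
  tab <- sample_table(X, rnorm(500))
  pca <- pca_compare(tab, n_components = 2, theta_load = 0.3)
  expect_setequal(pca$contained[[1]], c("A1", "A2"))
  l <- pca$loadings[, 1]
  expect_equal(abs(l[["A1"]]), abs(l[["A2"]]), tolerance = 1e-4)
})

test_that("the comparison report covers both methods", {
  feats <- extract_features(quick_model, quick_oracle$table,
                            feature_config())
  pca <- pca_compare(quick_oracle$table, n_components = 6)
  rep <- feature_report(feats, pca)
  expect_true(all(c("synergistic_feature", "pca") %in% rep$method))
  expect_equal(sum(rep$method == "pca"), 6L)
  # empty feature list: report degrades to the PCA side only
  empty <- feats
  empty$features <- list()
  rep0 <- feature_report(empty, pca)
  expect_true(all(rep0$method == "pca"))
  # identical contained sets overlap fully
  pc_match <- which(rep$method == "synergistic_feature")
  if (length(pc_match)) {
    ft <- feats$features[[1]]
    fake_pca <- pca
    fake_pca$contained[[1]] <- ft$contained
    rep2 <- feature_report(feats, fake_pca)
    expect_equal(rep2$best_pc_overlap[1], length(ft$contained))
  }
})

test_that("planted factor groups surface in the contained sets", {
  # two additive groups: at least one retained feature should stay inside
  # one of them in most replicates; check a fixed seed's model directly
  m <- manual_mlp(list(
    list(w = c(A1 = 1, A2 = 0.8), b = 0.5, out = 0.01),
    list(w = c(B5 = 1, B6 = -0.9), b = 0.2, out = 0.012)))
  feats <- extract_features(m, tiny_table, feature_config(theta_contrib = 1e-4))
  groups <- list(c("A1", "A2"), c("B5", "B6"))
  inside <- vapply(feats$features, function(ft)
    any(vapply(groups, function(g) all(ft$contained %in% g), logical(1))),
    logical(1))
  expect_true(any(inside))
})
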