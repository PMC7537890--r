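#' Configuration for synergistic-feature extraction
#'
#' @param theta_contrib a factor is "contained" in a feature when its
#'   weighted response range through that neuron reaches this threshold.
#' @param theta_weight features with output-layer weight magnitude below
#'   this are dropped (default 0: keep all, rank by weight).
#' @param sweep_points points per factor sweep used when computing
#'   contributions.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(theta_contrib = 3e-4, theta_weight = 0,
                           sweep_points = 201L) {
  structure(list(theta_contrib = theta_contrib, theta_weight = theta_weight,
                 sweep_points = as.integer(sweep_points)),
            class = "feature_config")
}

#' Extract synergistic features from the penultimate layer
#'
#' With a linear scalar output layer, predictions decompose exactly into
#' `sum_j w_j h_j + b` over the penultimate activations `h_j`, so each
#' penultimate neuron is a candidate feature. A feature's weight is `|w_j|`;
#' its contribution from factor `i` is `|w_j|` times the range of `h_j`
#' under factor `i`'s single-factor sweep (all other factors at their
#' sample means) — the weighted range of the response through that neuron.
#' Factors whose contribution reaches `theta_contrib` form the feature's
#' contained set; features with weight at least `theta_weight` and a
#' non-empty contained set are retained, sorted by weight descending.
#'
#' @param model an `esv_mlp` (linear scalar output required).
#' @param table the training [sample_table].
#' @param config a [feature_config].
#' @param analysis an [analysis_config] supplying sweep domains.
#' @return an object of class `synergistic_features`: a list with
#'   `features` (list of per-neuron records: `neuron`, `weight`,
#'   `contributions` named vector, `contained`, `label`), `contributions`
#'   (neuron x factor matrix over all 16 candidates) and `weights` (all
#'   `|w_j|`).
#' @export
extract_features <- function(model, table, config = feature_config(),
                             analysis = analysis_config()) {
  stopifnot(inherits(model, "esv_mlp"), inherits(table, "sample_table"))
  ow <- output_weights(model)
  w <- abs(ow$w)
  factors <- colnames(table$X)
  n_neuron <- length(w)
  contrib <- matrix(0, n_neuron, length(factors),
                    dimnames = list(NULL, factors))
  for (f in factors) {
    g <- sweep_grid(table, f, analysis, n_points = config$sweep_points)
    H <- penultimate_activations(model, sweep_inputs(table, f, g$xs_std))
    contrib[, f] <- w * (apply(H, 2L, max) - apply(H, 2L, min))
  }
  feats <- lapply(seq_len(n_neuron), function(j) {
    contained <- factors[contrib[j, ] >= config$theta_contrib]
    list(neuron = j, weight = w[j],
         contributions = contrib[j, ],
         contained = contained, label = NA_character_)
  })
  keep <- vapply(feats, function(ft)
    ft$weight >= config$theta_weight && length(ft$contained) > 0, logical(1))
  feats <- feats[keep]
  feats <- feats[order(-vapply(feats, `[[`, numeric(1), "weight"))]
  structure(list(features = feats, contributions = contrib, weights = w,
                 theta_contrib = config$theta_contrib),
            class = "synergistic_features")
}

#' @export
print.synergistic_features <- function(x, ...) {
  cat(sprintf("<synergistic_features> %d retained of %d penultimate neurons\n",
              length(x$features), length(x$weights)))
  for (ft in x$features)
    cat(sprintf("  neuron %2d  weight %.4g  contains: %s\n", ft$neuron,
                ft$weight, paste(ft$contained, collapse = " ")))
  invisible(x)
}

#' Principal component analysis of the factor table
#'
#' The conventional dimensionality-reduction baseline the penultimate-layer
#' features are contrasted with: PCA of the standardized factor matrix, with
#' each component's contained factors read off as those whose loading
#' magnitude reaches `theta_load`.
#'
#' @param table a [sample_table].
#' @param n_components components to report (default 6).
#' @param theta_load loading-magnitude threshold for containment.
#' @return an object of class `pca_result`: `loadings` (factors x
#'   components), `explained` (variance shares), `contained` (list of factor
#'   sets per component).
#' @export
pca_compare <- function(table, n_components = 6L, theta_load = 0.1) {
  stopifnot(inherits(table, "sample_table"))
  p <- ncol(table$X)
  if (n_components > p) stop("more components than factors")
  if (nrow(table$X) < n_components) stop("fewer samples than components")
  pc <- stats::prcomp(table$X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  contained <- lapply(k, function(j)
    rownames(loadings)[abs(loadings[, j]) >= theta_load])
  structure(list(loadings = loadings, explained = explained[k],
                 contained = contained, theta_load = theta_load),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components\n", ncol(x$loadings)))
  for (j in seq_along(x$contained))
    cat(sprintf("  PC%d (%.1f%% var) contains: %s\n", j,
                100 * x$explained[j], paste(x$contained[[j]], collapse = " ")))
  invisible(x)
}

#' Side-by-side report of synergistic features and principal components
#'
#' @param features a [synergistic_features] object (may hold zero features).
#' @param pca a [pca_result] from the same table.
#' @return data.frame: one row per feature or component with its
#'   weight / explained-variance share, contained factor set and, for
#'   features, the size of the overlap with the best-matching component.
#' @export
feature_report <- function(features, pca) {
  stopifnot(inherits(features, "synergistic_features"),
            inherits(pca, "pca_result"))
  if (length(features$features)) {
    feat_factors <- sort(unique(unlist(
      lapply(features$features, `[[`, "contained"))))
    if (!all(feat_factors %in% rownames(pca$loadings)))
      stop("feature and PCA factor sets do not match")
  }
  rows <- list()
  for (ft in features$features) {
    overlaps <- vapply(pca$contained, function(s)
      length(intersect(s, ft$contained)), integer(1))
    rows[[length(rows) + 1L]] <- data.frame(
      method = "synergistic_feature",
      id = sprintf("feature_%d", ft$neuron),
      score = ft$weight,
      contained = paste(ft$contained, collapse = ";"),
      n_contained = length(ft$contained),
      best_pc_overlap = if (length(overlaps)) max(overlaps) else 0L,
      stringsAsFactors = FALSE)
  }
  for (j in seq_along(pca$contained)) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = "pca", id = sprintf("PC%d", j),
      score = pca$explained[j],
      contained = paste(pca$contained[[j]], collapse = ";"),
      n_contained = length(pca$contained[[j]]),
      best_pc_overlap = NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
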