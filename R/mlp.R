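#' Surrogate network configuration
#'
#' The regression stack mapping the 23 standardized factors to standardized
#' ESV: dense 128 (linear) -> dropout -> dense 256 (tanh) -> dropout ->
#' dense 16 (ReLU) -> dropout -> dense 1 (linear). The first dense layer is
#' genuinely linear (no activation); the 16-unit ReLU layer is the
#' penultimate layer whose activations feed the synergistic-feature
#' decomposition, and the scalar output layer is linear so predictions
#' decompose exactly as `sum_j w_j h_j + b`.
#'
#' @param epochs training epochs (default 200).
#' @param split train fraction of the sample (default 0.7, seeded shuffle).
#' @param learning_rate,beta1,beta2,epsilon ADAM hyperparameters.
#' @param batch_size minibatch size.
#' @param dropout dropout rate applied after every hidden layer during
#'   training only; inference is deterministic.
#' @param seed seed for weight initialization, the train/test shuffle and
#'   the dropout masks.
#' @param layers hidden-layer spec: list of `list(units =, activation =)`
#'   with activation one of `"linear"`, `"tanh"`, `"relu"`. The scalar
#'   linear output layer is implicit and fixed.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(epochs = 200L, split = 0.7,
                       learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, batch_size = 32L, dropout = 0.3,
                       seed = 1L,
                       layers = list(list(units = 128L, activation = "linear"),
                                     list(units = 256L, activation = "tanh"),
                                     list(units = 16L, activation = "relu"))) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  acts <- vapply(layers, `[[`, character(1), "activation")
  if (!all(acts %in% c("linear", "tanh", "relu")))
    stop("unsupported activation")
  structure(list(epochs = as.integer(epochs), split = split,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 dropout = dropout, seed = as.integer(seed), layers = layers),
            class = "mlp_config")
}

act_fun <- function(name, z) {
  switch(name, linear = z, tanh = tanh(z), relu = pmax(z, 0))
}
# derivative wrt pre-activation, given activation value a and pre-act z
act_grad <- function(name, a, z) {
  switch(name, linear = 1, tanh = 1 - a * a, relu = (z > 0) * 1)
}

mlp_init <- function(sizes) {
  # seeded Glorot-uniform initialization; biases start at zero
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

mlp_forward <- function(W, b, acts, X) {
  # deterministic forward pass (no dropout); returns activations per layer
  A <- vector("list", length(W))
  cur <- X
  for (l in seq_along(W)) {
    cur <- act_fun(acts[l], add_bias(cur %*% W[[l]], b[[l]]))
    A[[l]] <- cur
  }
  A
}

#' Train the ESV surrogate network
#'
#' Splits the table by a seeded shuffle into train/test, minimizes MSE with
#' ADAM for the configured number of epochs (inverted dropout during
#' training), and evaluates Nash-Sutcliffe efficiency and RSR on the held-out
#' test set. The whole procedure is deterministic given the config seed:
#' initialization, split, batch order and dropout masks all draw from it.
#'
#' @param table a [sample_table] (standardized factors and response).
#' @param config an [mlp_config].
#' @return an object of class `esv_mlp`: weights `W`/`b`, activation names,
#'   the config, `history` (per-epoch train/test MSE), `split` (train/test
#'   indices), `metrics` (test-set [evaluate_fit]) and the training table's
#'   factor names.
#' @export
train_surrogate <- function(table, config = mlp_config()) {
  stopifnot(inherits(table, "sample_table"), inherits(config, "mlp_config"))
  X <- table$X; Y <- table$Y
  n <- nrow(X)
  if (n < 50L) stop("need at least 50 samples to train")
  if (anyNA(X) || anyNA(Y)) stop("NaNs in sample table")
  acts <- c(vapply(config$layers, `[[`, character(1), "activation"), "linear")
  sizes <- c(ncol(X), vapply(config$layers, function(l) as.integer(l$units),
                             integer(1)), 1L)
  L <- length(sizes) - 1L
  keep <- 1 - config$dropout

  withr::with_seed(config$seed, {
    perm <- sample.int(n)
    ntrain <- floor(config$split * n)
    tr <- perm[seq_len(ntrain)]; te <- perm[(ntrain + 1L):n]
    Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr]
    Xte <- X[te, , drop = FALSE]; Yte <- Y[te]

    par <- mlp_init(sizes)
    W <- par$W; b <- par$b
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    t_step <- 0L
    history <- matrix(NA_real_, config$epochs, 2L)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntrain)
      starts <- seq(1L, ntrain, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntrain)]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- Ytr[idx]
        m <- length(idx)
        # forward with inverted dropout on hidden activations
        Zs <- vector("list", L)        # pre-activations
        Araw <- vector("list", L)      # activations before dropout
        Adrop <- vector("list", L)     # activations after dropout (layer input)
        Ms <- vector("list", L - 1L)   # dropout masks, already scaled by 1/keep
        cur <- Xb
        for (l in seq_len(L)) {
          z <- add_bias(cur %*% W[[l]], b[[l]])
          a <- act_fun(acts[l], z)
          Zs[[l]] <- z; Araw[[l]] <- a
          if (l < L && config$dropout > 0) {
            mask <- (matrix(stats::runif(length(a)), nrow(a), ncol(a)) >=
                       config$dropout) / keep
            Ms[[l]] <- mask
            a <- a * mask
          }
          Adrop[[l]] <- a
          cur <- a
        }
        pred <- Adrop[[L]][, 1L]
        # backward: d MSE / d pred
        delta <- matrix(2 * (pred - yb) / m, m, 1L)
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in L:1L) {
          inp <- if (l == 1L) Xb else Adrop[[l - 1L]]
          gW[[l]] <- crossprod(inp, delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) {
            dA <- delta %*% t(W[[l]])
            if (config$dropout > 0) dA <- dA * Ms[[l - 1L]]
            delta <- dA * act_grad(acts[l - 1L], Araw[[l - 1L]], Zs[[l - 1L]])
          }
        }
        # ADAM update
        t_step <- t_step + 1L
        bc1 <- 1 - config$beta1^t_step; bc2 <- 1 - config$beta2^t_step
        for (l in seq_len(L)) {
          mW[[l]] <- config$beta1 * mW[[l]] + (1 - config$beta1) * gW[[l]]
          vW[[l]] <- config$beta2 * vW[[l]] + (1 - config$beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - config$learning_rate * (mW[[l]] / bc1) /
            (sqrt(vW[[l]] / bc2) + config$epsilon)
          mb[[l]] <- config$beta1 * mb[[l]] + (1 - config$beta1) * gb[[l]]
          vb[[l]] <- config$beta2 * vb[[l]] + (1 - config$beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] - config$learning_rate * (mb[[l]] / bc1) /
            (sqrt(vb[[l]] / bc2) + config$epsilon)
        }
      }
      ptr <- mlp_forward(W, b, acts, Xtr)[[L]][, 1L]
      pte <- mlp_forward(W, b, acts, Xte)[[L]][, 1L]
      history[epoch, ] <- c(mean((ptr - Ytr)^2), mean((pte - Yte)^2))
      if (!all(is.finite(history[epoch, ])))
        stop("training diverged: non-finite loss at epoch ", epoch)
    }
  })

  model <- structure(
    list(W = W, b = b, activations = acts, config = config,
         feature_names = colnames(X),
         history = data.frame(epoch = seq_len(config$epochs),
                              train_mse = history[, 1L],
                              test_mse = history[, 2L]),
         split = list(train = tr, test = te)),
    class = "esv_mlp")
  model$metrics <- evaluate_fit(Yte, predict(model, Xte))
  model
}

#' @export
print.esv_mlp <- function(x, ...) {
  cat(sprintf("<esv_mlp> %s -> 1 (linear), %d epochs",
              paste(vapply(x$config$layers, function(l)
                sprintf("%d/%s", l$units, l$activation), character(1)),
                collapse = " -> "),
              x$config$epochs), "\n")
  if (!is.null(x$metrics))
    cat(sprintf("  test NSE %.3f, RSR %.3f (%s)\n", x$metrics$nse,
                x$metrics$rsr, x$metrics$grade))
  invisible(x)
}

#' Predict standardized ESV for a factor matrix
#'
#' Deterministic inference: dropout is inactive, so repeated calls on the
#' same input are bit-identical.
#'
#' @param object an `esv_mlp` from [train_surrogate].
#' @param newdata numeric matrix with the training factor columns (matched
#'   by name when column names are present).
#' @param ... unused.
#' @return numeric vector of predictions on the standardized ESV scale.
#' @export
predict.esv_mlp <- function(object, newdata, ...) {
  X <- check_model_input(object, newdata)
  A <- mlp_forward(object$W, object$b, object$activations, X)
  A[[length(A)]][, 1L]
}

check_model_input <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  p <- nrow(model$W[[1L]])
  if (ncol(X) != p)
    stop("expected ", p, " factor columns, got ", ncol(X))
  if (!is.null(colnames(X)) && !is.null(model$feature_names)) {
    if (!setequal(colnames(X), model$feature_names))
      stop("factor columns do not match the training factors")
    X <- X[, model$feature_names, drop = FALSE]
  }
  X
}

#' Activations of the penultimate (16-unit ReLU) layer
#'
#' The last hidden layer before the linear scalar output; with output weights
#' `w` and bias `b0`, `penultimate_activations(m, X) %*% w + b0` reproduces
#' `predict(m, X)` exactly, which is the identity the synergistic-feature
#' decomposition rests on.
#'
#' @param model an `esv_mlp`.
#' @param X factor matrix as for [predict.esv_mlp].
#' @return n x (penultimate width) matrix of non-negative activations.
#' @export
penultimate_activations <- function(model, X) {
  stopifnot(inherits(model, "esv_mlp"))
  L <- length(model$W)
  if (model$activations[L] != "linear" || ncol(model$W[[L]]) != 1L)
    stop("feature extraction requires a linear scalar output layer")
  X <- check_model_input(model, X)
  mlp_forward(model$W, model$b, model$activations, X)[[L - 1L]]
}

#' Output-layer weights of the surrogate
#' @param model an `esv_mlp`.
#' @return list with `w` (vector, one weight per penultimate unit) and `b`
#'   (scalar output bias).
#' @export
output_weights <- function(model) {
  stopifnot(inherits(model, "esv_mlp"))
  L <- length(model$W)
  list(w = model$W[[L]][, 1L], b = model$b[[L]])
}

#' Nash-Sutcliffe efficiency and RSR of predictions
#'
#' `NSE = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`; `RSR` is RMSE
#' divided by the SD of the observations. Both use population (n)
#' normalization, so the identity `NSE = 1 - RSR^2` is exact on any finite
#' input. Performance is graded "satisfactory" when NSE > 0.5 and
#' RSR <= 0.70, following the usual hydrological criteria.
#'
#' @param obs observed values (non-constant, length >= 2).
#' @param pred predicted values, same length.
#' @return list with `nse`, `rsr`, `rmse` and `grade`.
#' @export
evaluate_fit <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2L) stop("need at least 2 observations")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("constant observations: NSE/RSR undefined")
  sse <- sum((obs - pred)^2)
  nse <- 1 - sse / sst
  rmse <- sqrt(sse / length(obs))
  rsr <- rmse / sqrt(sst / length(obs))
  list(nse = nse, rsr = rsr, rmse = rmse,
       grade = if (nse > 0.5 && rsr <= 0.70) "satisfactory"
               else "unsatisfactory")
}
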