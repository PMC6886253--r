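# Stacked autoencoder: symmetric encoder/decoder trained by SGD on the
# mean squared reconstruction error; the bottleneck supplies the deep
# 64-dim sequence features.

#' Stacked-autoencoder configuration
#'
#' @param layer_sizes Hidden widths, encoder through decoder (default
#'   256, 128, 64, 128, 256). Must be palindromic; the middle entry is the
#'   bottleneck.
#' @param activation Hidden nonlinearity: "relu" (default), "sigmoid" or
#'   "tanh". The output layer is linear (inputs are z-scored, not bounded
#'   to \[0,1\]).
#' @param epochs SGD passes (default 50).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate SGD rate (default 0.01).
#' @param seed RNG seed.
#' @return An `sae_config` list.
#' @export
sae_config <- function(layer_sizes = c(256L, 128L, 64L, 128L, 256L),
                       activation = c("relu", "sigmoid", "tanh"),
                       epochs = 50L, batch_size = 64L, learning_rate = 0.01,
                       seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 1L, all(layer_sizes >= 1L),
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  if (!identical(layer_sizes, rev(layer_sizes)))
    stop("layer_sizes must be palindromic (equal encoder and decoder widths)")
  if (length(layer_sizes) %% 2L == 0L)
    stop("layer_sizes needs an odd count: encoder, bottleneck, mirrored decoder")
  structure(list(layer_sizes = layer_sizes,
                 activation = match.arg(activation),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "sae_config")
}

sae_check_input <- function(X, width = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input matrix")
  if (!is.null(width) && ncol(X) != width)
    stop("input width ", ncol(X), " does not match model width ", width)
  X
}

#' Train a stacked autoencoder on descriptor vectors
#'
#' Columns are z-scored on the training split (statistics stored in the
#' model and applied to validation and later inputs); the network is then
#' trained by minibatch SGD to minimize mean squared reconstruction error.
#' Per-epoch train and validation MSE are recorded.
#'
#' @param X Numeric matrix, one protein per row (468 columns under the
#'   default descriptor set).
#' @param cfg An [sae_config()].
#' @param val_fraction Fraction of rows held out for the validation curve
#'   (default 0.1; 0 disables).
#' @return An `sae_model` with fields `net`, `config`, `center`, `scale`,
#'   `history` (data frame epoch/train_mse/val_mse), `input_width`.
#' @export
train_sae <- function(X, cfg = sae_config(), val_fraction = 0.1) {
  X <- sae_check_input(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to train")
  stopifnot(val_fraction >= 0, val_fraction < 1)
  set.seed(cfg$seed)
  n <- nrow(X)
  n_val <- floor(n * val_fraction)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  center <- colMeans(X[tr_idx, , drop = FALSE])
  scale <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  Ztr <- Z[tr_idx, , drop = FALSE]
  Zval <- Z[val_idx, , drop = FALSE]

  sizes <- c(ncol(X), cfg$layer_sizes, ncol(X))
  net <- nn_init(sizes, cfg$activation)
  mse_of <- function(M) {
    if (nrow(M) == 0L) return(NA_real_)
    out <- nn_forward(net, M, cfg$activation, "linear")$acts[[length(sizes)]]
    mean((M - out)^2)
  }
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_mse = NA_real_,
                     val_mse = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ep_sse <- 0
    for (batch in nn_minibatches(nrow(Ztr), cfg$batch_size)) {
      B <- Ztr[batch, , drop = FALSE]
      fwd <- nn_forward(net, B, cfg$activation, "linear")
      out <- fwd$acts[[length(sizes)]]
      resid <- out - B
      ep_sse <- ep_sse + sum(resid^2)
      delta <- 2 * resid / length(B)
      grads <- nn_backward(net, fwd, delta, cfg$activation)
      net <- nn_sgd_step(net, grads, cfg$learning_rate)
    }
    # training MSE is the running minibatch average (pre-update residuals);
    # validation is an exact pass
    hist$train_mse[ep] <- ep_sse / length(Ztr)
    hist$val_mse[ep] <- mse_of(Zval)
  }
  structure(list(net = net, config = cfg, center = center, scale = scale,
                 history = hist, input_width = ncol(X)),
            class = "sae_model")
}

#' @export
print.sae_model <- function(x, ...) {
  cat("<sae_model>", x$input_width, "->",
      paste(x$config$layer_sizes, collapse = "-"), "->", x$input_width,
      "| final train MSE",
      signif(utils::tail(x$history$train_mse, 1), 4), "\n")
  invisible(x)
}

sae_bottleneck_layer <- function(model) (length(model$config$layer_sizes) + 1L) %/% 2L

#' Encode descriptor vectors to the bottleneck representation
#'
#' Deterministic forward pass through the encoder layers only (z-scoring
#' applied with the training statistics).
#'
#' @param model An `sae_model`.
#' @param v Numeric vector or matrix of rows matching the training width.
#' @return Matrix n x bottleneck (64 under defaults); a single vector in
#'   yields a 1-row matrix.
#' @export
sae_encode <- function(model, v) {
  X <- if (is.null(dim(v))) matrix(v, nrow = 1) else as.matrix(v)
  X <- sae_check_input(X, model$input_width)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  n_enc <- sae_bottleneck_layer(model)
  a <- Z
  for (l in seq_len(n_enc)) {
    z <- add_bias(a %*% model$net$W[[l]], model$net$b[[l]])
    a <- nn_act(z, model$config$activation)
  }
  rownames(a) <- rownames(X)
  a
}

#' Reconstruct descriptor vectors through the full autoencoder
#'
#' @inheritParams sae_encode
#' @return Matrix n x input width, mapped back to the original column
#'   scales (inverse of the training z-score).
#' @export
sae_reconstruct <- function(model, v) {
  X <- if (is.null(dim(v))) matrix(v, nrow = 1) else as.matrix(v)
  X <- sae_check_input(X, model$input_width)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  L <- length(model$net$W)
  out <- nn_forward(model$net, Z, model$config$activation,
                    "linear")$acts[[L + 1L]]
  out <- sweep(sweep(out, 2, model$scale, `*`), 2, model$center, `+`)
  rownames(out) <- rownames(X)
  out
}

#' Mean squared error between observed and predicted values
#'
#' @param y,yhat Numeric vectors or matrices of matching shape.
#' @return Mean of squared differences over all entries.
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((as.numeric(y) - as.numeric(yhat))^2)
}

#' Save an SAE checkpoint (portable JSON: widths, weights, z-score
#' statistics, config, loss history)
#' @param model An `sae_model`.
#' @param path Output .json path.
#' @export
write_sae <- function(model, path) {
  obj <- list(
    type = "sae_model",
    config = unclass(model$config),
    center = model$center, scale = model$scale,
    input_width = model$input_width,
    history = model$history,
    W = model$net$W,
    b = model$net$b
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an SAE checkpoint written by [write_sae()]
#' @param path Checkpoint path.
#' @return An `sae_model`.
#' @export
read_sae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "sae_model"))
  cfg <- do.call(sae_config, obj$config[c("layer_sizes", "activation",
                                          "epochs", "batch_size",
                                          "learning_rate", "seed")])
  net <- list(
    W = lapply(obj$W, function(w) as.matrix(w)),
    b = lapply(obj$b, as.numeric),
    sizes = c(obj$input_width, cfg$layer_sizes, obj$input_width)
  )
  structure(list(net = net, config = cfg, center = obj$center,
                 scale = obj$scale, history = obj$history,
                 input_width = obj$input_width),
            class = "sae_model")
}
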