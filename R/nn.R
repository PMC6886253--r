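# Minimal dense feed-forward engine (vectorized base R) used by the stacked
# autoencoder and the supervised heads. Row-major batches: X is n x d_in,
# layer l maps through W[[l]] (d_{l-1} x d_l) and bias b[[l]].

# column-wise bias add without sweep()'s copies (hot path)
add_bias <- function(z, b) z + rep(b, each = nrow(z))

nn_act <- function(z, kind) {
  switch(kind,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         linear = z,
         softmax = {
           e <- exp(z - apply(z, 1, max))
           e / rowSums(e)
         },
         stop("unknown activation: ", kind))
}

nn_act_grad <- function(a, kind) {
  # derivative expressed in terms of the activation value a
  switch(kind,
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         linear = array(1, dim(a)),
         stop("no elementwise gradient for ", kind))
}

nn_init <- function(sizes, hidden_act = "relu") {
  # He initialization for relu, Glorot otherwise; biases zero
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sdv <- if (hidden_act == "relu") sqrt(2 / fan_in)
           else sqrt(2 / (fan_in + sizes[l + 1]))
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], 0, sdv),
                     fan_in, sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

nn_forward <- function(net, X, hidden_act, out_act,
                       dropout = 0, training = FALSE) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- add_bias(acts[[l]] %*% net$W[[l]], net$b[[l]])
    a <- nn_act(z, if (l == L) out_act else hidden_act)
    if (l < L && training && dropout > 0) {
      m <- matrix(stats::rbinom(length(a), 1L, 1 - dropout), nrow(a)) /
        (1 - dropout)
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1]] <- a
  }
  list(acts = acts, masks = masks)
}

# delta_out: gradient of the loss w.r.t. the output PRE-activation (for the
# canonical pairings linear+MSE, sigmoid+BCE, softmax+CCE this is simply
# (prediction - target) times the loss normalization).
nn_backward <- function(net, fwd, delta_out, hidden_act) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- delta_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      delta <- delta * nn_act_grad(fwd$acts[[l]], hidden_act)
    }
  }
  list(W = gW, b = gb)
}

nn_sgd_step <- function(net, grads, lr) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] - lr * grads$W[[l]]
    net$b[[l]] <- net$b[[l]] - lr * grads$b[[l]]
  }
  net
}

nn_minibatches <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
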