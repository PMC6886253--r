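# Late fusion of the two modalities and the two supervised heads:
# a twin-branch interaction identifier (binary cross entropy) and a
# multi-family DNN classifier (categorical cross entropy).

#' Fuse topological and deep-sequence features
#'
#' Concatenation `[topological | deep-sequence]`, 128 + 64 = 192 under the
#' default dimensions. A missing topological vector (cold-start node) is
#' passed in as a zero block by [embedding_vectors()].
#'
#' @param topo Numeric vector (or matrix of rows), topological embedding.
#' @param seq Numeric vector (or matrix of rows), SAE bottleneck features.
#' @return Fused vector/matrix of width `dim(topo) + dim(seq)`.
#' @export
fuse_features <- function(topo, seq) {
  if (is.null(dim(topo)) != is.null(dim(seq)))
    stop("fuse both as vectors or both as matrices")
  if (is.null(dim(topo))) return(c(topo, seq))
  if (nrow(topo) != nrow(seq)) stop("row mismatch between modalities")
  out <- cbind(topo, seq)
  rownames(out) <- rownames(topo)
  out
}

#' Build the fused feature matrix for a set of proteins
#'
#' @param emb An `embedding_matrix` from [train_cbow()].
#' @param sae An `sae_model` from [train_sae()].
#' @param features Descriptor matrix (rows = proteins, 468 columns).
#' @param ids Protein IDs (default: rownames of `features`).
#' @param cold_start Policy for nodes absent from walks; see
#'   [embedding_vectors()].
#' @return Matrix ids x (dim_topo + bottleneck).
#' @export
fused_matrix <- function(emb, sae, features, ids = rownames(features),
                         cold_start = "zero") {
  topo <- embedding_vectors(emb, ids, cold_start)
  seqf <- sae_encode(sae, features[ids, , drop = FALSE])
  fuse_features(topo, seqf)
}

clip_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Binary cross-entropy loss
#' @param y 0/1 labels.
#' @param yhat Predicted probabilities (clipped to \[1e-7, 1-1e-7\]).
#' @return Mean negative log-likelihood.
#' @export
bce_loss <- function(y, yhat) {
  yhat <- clip_prob(yhat)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Categorical cross-entropy loss
#' @param Y One-hot matrix (n x C) or integer class labels in 1..C.
#' @param P Predicted probability matrix (n x C).
#' @return Mean negative log-likelihood over examples.
#' @export
cce_loss <- function(Y, P) {
  P <- clip_prob(P)
  if (is.null(dim(Y))) {
    -mean(log(P[cbind(seq_len(nrow(P)), as.integer(Y))]))
  } else {
    -mean(rowSums(Y * log(P)))
  }
}

#' Twin-branch PPI classifier configuration
#'
#' @param branch_hidden Hidden widths of each protein branch (default 64).
#' @param merge_hidden Width of the fully connected layer after
#'   concatenating the two branch outputs (default 64).
#' @param epochs,batch_size,learning_rate SGD settings (defaults 200, 64,
#'   0.01).
#' @param seed RNG seed.
#' @param symmetrize Augment each training pair with its swap and average
#'   the two pair orders at prediction, making the head order-insensitive
#'   (default TRUE; disable for the strict asymmetric architecture).
#' @return A `ppi_classifier_config` list.
#' @export
ppi_classifier_config <- function(branch_hidden = 64L, merge_hidden = 64L,
                                  epochs = 200L, batch_size = 64L,
                                  learning_rate = 0.01, seed = 1L,
                                  symmetrize = TRUE) {
  stopifnot(all(branch_hidden >= 1L), merge_hidden >= 1L, epochs >= 1L,
            batch_size >= 1L, learning_rate > 0)
  structure(list(branch_hidden = as.integer(branch_hidden),
                 merge_hidden = as.integer(merge_hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 symmetrize = isTRUE(symmetrize)),
            class = "ppi_classifier_config")
}

ppi_forward <- function(par, Xm, Xn) {
  am <- Xm; an <- Xn
  acts_m <- list(am); acts_n <- list(an)
  for (l in seq_along(par$branch_m$W)) {
    am <- nn_act(sweep(am %*% par$branch_m$W[[l]], 2, par$branch_m$b[[l]], `+`), "relu")
    an <- nn_act(sweep(an %*% par$branch_n$W[[l]], 2, par$branch_n$b[[l]], `+`), "relu")
    acts_m[[l + 1L]] <- am; acts_n[[l + 1L]] <- an
  }
  C <- cbind(am, an)
  H <- nn_act(sweep(C %*% par$Wh, 2, par$bh, `+`), "relu")
  yhat <- as.vector(nn_act(H %*% par$wo + par$bo, "sigmoid"))
  list(acts_m = acts_m, acts_n = acts_n, C = C, H = H, yhat = yhat)
}

#' Train the twin-branch protein interaction identifier
#'
#' Two branch networks (one per protein, shared architecture, separate
#' weights) map each fused protein vector through ReLU layers; their
#' outputs are concatenated into one fully connected ReLU layer feeding a
#' single sigmoid unit. Trained by minibatch SGD on binary cross entropy.
#'
#' @param pairs Data frame with columns `id_m`, `id_n`, `label` (0/1).
#' @param features Matrix of fused features, rownames = protein IDs.
#' @param cfg A [ppi_classifier_config()].
#' @return A `ppi_model` with the trained parameters, config, input width
#'   and per-epoch training loss.
#' @export
train_ppi_classifier <- function(pairs, features, cfg = ppi_classifier_config()) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("id_m", "id_n", "label") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$id_m, pairs$id_n)), rownames(features))
  if (length(missing) > 0)
    stop("no features for protein(s): ", paste(utils::head(missing, 5), collapse = ", "))
  y <- as.numeric(pairs$label)
  if (length(unique(y)) < 2L)
    stop("training set must contain both interaction classes")
  if (cfg$symmetrize) {
    pairs <- rbind(pairs, data.frame(id_m = pairs$id_n, id_n = pairs$id_m,
                                     label = pairs$label))
    y <- c(y, y)
  }
  Xm <- features[pairs$id_m, , drop = FALSE]
  Xn <- features[pairs$id_n, , drop = FALSE]
  d <- ncol(features)

  set.seed(cfg$seed)
  bsizes <- c(d, cfg$branch_hidden)
  par <- list(branch_m = nn_init(bsizes, "relu"),
              branch_n = nn_init(bsizes, "relu"))
  nb <- utils::tail(cfg$branch_hidden, 1)
  par$Wh <- matrix(stats::rnorm(2 * nb * cfg$merge_hidden, 0, sqrt(2 / (2 * nb))),
                   2 * nb, cfg$merge_hidden)
  par$bh <- numeric(cfg$merge_hidden)
  par$wo <- matrix(stats::rnorm(cfg$merge_hidden, 0, sqrt(2 / cfg$merge_hidden)),
                   cfg$merge_hidden, 1)
  par$bo <- 0

  n <- nrow(Xm)
  loss_hist <- numeric(cfg$epochs)
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0
    for (batch in nn_minibatches(n, cfg$batch_size)) {
      Bm <- Xm[batch, , drop = FALSE]; Bn <- Xn[batch, , drop = FALSE]
      yb <- y[batch]
      f <- ppi_forward(par, Bm, Bn)
      ep_loss <- ep_loss + bce_loss(yb, f$yhat) * length(batch)
      nbt <- length(batch)
      delta_o <- matrix((f$yhat - yb) / nbt, ncol = 1)
      gwo <- crossprod(f$H, delta_o); gbo <- sum(delta_o)
      dH <- (delta_o %*% t(par$wo)) * (f$H > 0)
      gWh <- crossprod(f$C, dH); gbh <- colSums(dH)
      dC <- dH %*% t(par$Wh)
      dm <- dC[, seq_len(nb), drop = FALSE] * (f$acts_m[[length(f$acts_m)]] > 0)
      dn <- dC[, nb + seq_len(nb), drop = FALSE] * (f$acts_n[[length(f$acts_n)]] > 0)
      for (side in c("branch_m", "branch_n")) {
        delta <- if (side == "branch_m") dm else dn
        acts <- if (side == "branch_m") f$acts_m else f$acts_n
        br <- par[[side]]
        for (l in rev(seq_along(br$W))) {
          gW <- crossprod(acts[[l]], delta); gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(br$W[[l]])) * (acts[[l]] > 0)
          br$W[[l]] <- br$W[[l]] - lr * gW
          br$b[[l]] <- br$b[[l]] - lr * gb
        }
        par[[side]] <- br
      }
      par$Wh <- par$Wh - lr * gWh; par$bh <- par$bh - lr * gbh
      par$wo <- par$wo - lr * gwo; par$bo <- par$bo - lr * gbo
    }
    loss_hist[ep] <- ep_loss / n
  }
  structure(list(par = par, config = cfg, input_width = d,
                 loss_history = loss_hist),
            class = "ppi_model")
}

#' Predict the interaction probability for a protein pair
#'
#' @param model A trained `ppi_model`.
#' @param m_feat,n_feat Fused feature vectors (or matrices of rows) of the
#'   two proteins.
#' @return Probability in \[0,1\] (vector for matrix input). With
#'   `symmetrize` the two pair orders are averaged, so
#'   `predict_interaction(m, n) == predict_interaction(n, m)`.
#' @export
predict_interaction <- function(model, m_feat, n_feat) {
  if (!inherits(model, "ppi_model")) stop("model is not a trained ppi_model")
  Xm <- if (is.null(dim(m_feat))) matrix(m_feat, nrow = 1) else as.matrix(m_feat)
  Xn <- if (is.null(dim(n_feat))) matrix(n_feat, nrow = 1) else as.matrix(n_feat)
  if (ncol(Xm) != model$input_width || ncol(Xn) != model$input_width)
    stop("feature width mismatch: expected ", model$input_width)
  p <- ppi_forward(model$par, Xm, Xn)$yhat
  if (model$config$symmetrize)
    p <- (p + ppi_forward(model$par, Xn, Xm)$yhat) / 2
  p
}

#' Family DNN classifier configuration
#'
#' @param hidden Hidden widths of the three-layer DNN before the softmax
#'   output (default 128, 64).
#' @param epochs,batch_size,learning_rate,dropout SGD settings (defaults
#'   200, 64, 0.01, 0.5).
#' @param seed RNG seed.
#' @return A `family_classifier_config` list.
#' @export
family_classifier_config <- function(hidden = c(128L, 64L), epochs = 200L,
                                     batch_size = 64L, learning_rate = 0.01,
                                     dropout = 0.5, seed = 1L) {
  stopifnot(all(hidden >= 1L), epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, dropout >= 0, dropout < 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 seed = as.integer(seed)),
            class = "family_classifier_config")
}

#' Train the multi-family DNN classifier
#'
#' Three-layer DNN (two ReLU hidden layers with dropout, softmax output of
#' width C) trained by minibatch SGD on categorical cross entropy.
#'
#' @param examples Data frame with columns `id`, `family`.
#' @param features Matrix of fused features, rownames = protein IDs.
#' @param cfg A [family_classifier_config()].
#' @return A `family_model` with the trained network, label set, config and
#'   per-epoch training loss.
#' @export
train_family_classifier <- function(examples, features,
                                    cfg = family_classifier_config()) {
  examples <- as.data.frame(examples)
  stopifnot(all(c("id", "family") %in% names(examples)))
  missing <- setdiff(examples$id, rownames(features))
  if (length(missing) > 0)
    stop("no features for protein(s): ", paste(utils::head(missing, 5), collapse = ", "))
  labels <- sort(unique(as.character(examples$family)))
  if (length(labels) < 2L) stop("need at least 2 family classes")
  counts <- table(as.character(examples$family))
  if (any(counts < 2L))
    stop("every family needs >= 2 examples (offender: ",
         names(counts)[which.min(counts)], "); filter with filter_families()")
  yi <- match(as.character(examples$family), labels)
  X <- features[examples$id, , drop = FALSE]
  C <- length(labels)

  set.seed(cfg$seed)
  sizes <- c(ncol(X), cfg$hidden, C)
  net <- nn_init(sizes, "relu")
  n <- nrow(X)
  loss_hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0
    for (batch in nn_minibatches(n, cfg$batch_size)) {
      B <- X[batch, , drop = FALSE]
      fwd <- nn_forward(net, B, "relu", "softmax",
                        dropout = cfg$dropout, training = TRUE)
      P <- fwd$acts[[length(sizes)]]
      ep_loss <- ep_loss + cce_loss(yi[batch], P) * length(batch)
      delta <- P
      delta[cbind(seq_along(batch), yi[batch])] <-
        delta[cbind(seq_along(batch), yi[batch])] - 1
      delta <- delta / length(batch)
      grads <- nn_backward(net, fwd, delta, "relu")
      net <- nn_sgd_step(net, grads, cfg$learning_rate)
    }
    loss_hist[ep] <- ep_loss / n
  }
  structure(list(net = net, labels = labels, config = cfg,
                 input_width = ncol(X), loss_history = loss_hist),
            class = "family_model")
}

#' Predict family membership probabilities
#'
#' @param model A trained `family_model`.
#' @param feats Fused feature vector or matrix of rows.
#' @return List with `prob` (n x C softmax matrix, columns named by family
#'   label, rows summing to 1) and `label` (argmax class per row).
#' @export
predict_family <- function(model, feats) {
  if (!inherits(model, "family_model")) stop("model is not a trained family_model")
  X <- if (is.null(dim(feats))) matrix(feats, nrow = 1) else as.matrix(feats)
  if (ncol(X) != model$input_width)
    stop("feature width mismatch: expected ", model$input_width)
  L <- length(model$net$W)
  P <- nn_forward(model$net, X, "relu", "softmax")$acts[[L + 1L]]
  colnames(P) <- model$labels
  rownames(P) <- rownames(X)
  list(prob = P, label = model$labels[max.col(P, ties.method = "first")])
}

#' Filter family examples to sufficiently large families
#'
#' Retains only families with strictly more than `min_count` members
#' (default 15, matching the "more than 15 samples" rule).
#'
#' @param examples Data frame with columns `id`, `family`.
#' @param min_count Strict lower bound on family size (default 15).
#' @return List with `examples` (filtered data frame) and `families`
#'   (retained label set).
#' @export
filter_families <- function(examples, min_count = 15L) {
  examples <- as.data.frame(examples)
  stopifnot(min_count >= 0L)
  counts <- table(as.character(examples$family))
  keep <- names(counts)[counts > min_count]
  list(examples = examples[as.character(examples$family) %in% keep, ,
                           drop = FALSE],
       families = sort(keep))
}

#' Read/write the pair TSV dialect (`id_m  id_n  label`)
#' @param path TSV path.
#' @return Data frame with columns id_m, id_n, label.
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("id_m", "id_n", "label"),
                    colClasses = c("character", "character", "integer"))
}

#' @rdname read_pairs
#' @param pairs Data frame with columns id_m, id_n, label.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_m", "id_n", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write the family TSV dialect (`id  family`)
#' @param path TSV path.
#' @return Data frame with columns id, family.
#' @export
read_family_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("id", "family"),
                    colClasses = c("character", "character"))
}

#' @rdname read_family_table
#' @param examples Data frame with columns id, family.
#' @export
write_family_table <- function(examples, path) {
  utils::write.table(examples[, c("id", "family")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
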