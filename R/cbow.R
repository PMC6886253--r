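# Continuous bag-of-words embedding over metapath corpora.
#
# Two estimation modes share the same negative log-likelihood objective on
# the softmax over node vocabulary: "full" evaluates the exact softmax
# (tractable for the small vocabularies used in tests), "negative" uses
# negative sampling with k noise nodes drawn from the unigram^0.75
# distribution, the standard word2vec approximation.

#' CBOW training configuration
#'
#' @param dim Embedding size (default 128).
#' @param window Context radius (default 1).
#' @param epochs Passes over the walk corpus (default 10).
#' @param learning_rate Initial SGD rate; decays linearly to 1e-4 of itself.
#' @param seed RNG seed.
#' @param softmax_mode "negative" (sampling, default) or "full" (exact).
#' @param negative Number of noise samples per center in negative mode.
#' @return A `cbow_config` list.
#' @export
cbow_config <- function(dim = 128L, window = 1L, epochs = 10L,
                        learning_rate = 0.05, seed = 1L,
                        softmax_mode = c("negative", "full"), negative = 5L) {
  stopifnot(dim >= 1L, window >= 1L, epochs >= 1L, learning_rate > 0,
            negative >= 1L)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed),
                 softmax_mode = match.arg(softmax_mode),
                 negative = as.integer(negative)),
            class = "cbow_config")
}

#' Train CBOW node embeddings on a walk corpus
#'
#' Context vectors (input embeddings) are averaged to predict the center
#' node through a softmax over the vocabulary; parameters are updated by
#' SGD on the negative log-likelihood. The returned matrix holds the input
#' embeddings, the representation used for similarity queries.
#'
#' @param paths List of node-ID walks (see [generate_metapaths()]).
#' @param cfg A [cbow_config()].
#' @return An `embedding_matrix`: list with `vectors` (|V| x dim matrix,
#'   rownames = node IDs), `vocabulary`, `loss_history` (mean NLL per epoch;
#'   exact in full mode, the sampled objective in negative mode), `config`.
#' @export
train_cbow <- function(paths, cfg = cbow_config()) {
  pairs <- context_pairs(paths, cfg$window)
  if (length(pairs) == 0L)
    stop("no trainable (center, context) pairs: corpus empty or all walks length 1")
  vocab <- sort(unique(unlist(paths, use.names = FALSE)))
  if (length(vocab) < 2L)
    stop("vocabulary of size ", length(vocab), ": no context structure to learn")
  V <- length(vocab)
  idx <- stats::setNames(seq_len(V), vocab)
  centers <- vapply(pairs, function(x) idx[[x$center]], integer(1))
  ctxs <- lapply(pairs, function(x) unname(idx[x$contexts]))

  set.seed(cfg$seed)
  d <- cfg$dim
  W_in <- matrix(stats::runif(V * d, -0.5 / d, 0.5 / d), V, d)  # input (context)
  W_out <- matrix(0, V, d)                                      # output (center)
  # unigram^0.75 noise distribution over centers
  freq <- tabulate(centers, nbins = V)
  noise_p <- (freq + 1)^0.75
  noise_p <- noise_p / sum(noise_p)

  n_pairs <- length(pairs)
  total_steps <- cfg$epochs * n_pairs
  lr0 <- cfg$learning_rate
  loss_hist <- numeric(cfg$epochs)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_pairs)
    ep_loss <- 0
    for (i in ord) {
      step <- step + 1L
      lr <- lr0 * max(1e-4, 1 - step / total_steps)
      ctx <- ctxs[[i]]
      ci <- centers[i]
      h <- if (length(ctx) == 1L) W_in[ctx, ] else colMeans(W_in[ctx, , drop = FALSE])
      if (cfg$softmax_mode == "full") {
        sc <- as.vector(W_out %*% h)
        sc <- sc - max(sc)
        p <- exp(sc); p <- p / sum(p)
        ep_loss <- ep_loss - log(max(p[ci], 1e-300))
        g <- p
        g[ci] <- g[ci] - 1                       # dL/dscore
        dh <- as.vector(crossprod(W_out, g))
        W_out <- W_out - lr * tcrossprod(g, h)
      } else {
        neg <- sample.int(V, cfg$negative, replace = TRUE, prob = noise_p)
        neg <- neg[neg != ci]
        targ <- c(ci, neg)
        lab <- c(1, numeric(length(neg)))
        sc <- as.vector(W_out[targ, , drop = FALSE] %*% h)
        sig <- 1 / (1 + exp(-sc))
        ep_loss <- ep_loss - sum(lab * log(pmax(sig, 1e-12)) +
                                   (1 - lab) * log(pmax(1 - sig, 1e-12)))
        g <- sig - lab
        dh <- as.vector(crossprod(W_out[targ, , drop = FALSE], g))
        W_out[targ, ] <- W_out[targ, , drop = FALSE] - lr * tcrossprod(g, h)
      }
      W_in[ctx, ] <- W_in[ctx, , drop = FALSE] -
        matrix(lr * dh / length(ctx), length(ctx), d, byrow = TRUE)
    }
    if (cfg$softmax_mode == "full") {
      # exact corpus NLL at the end of the epoch (vectorized)
      H <- t(vapply(ctxs, function(ctx) {
        if (length(ctx) == 1L) W_in[ctx, ] else colMeans(W_in[ctx, , drop = FALSE])
      }, numeric(d)))
      S <- H %*% t(W_out)
      S <- S - apply(S, 1, max)
      logZ <- log(rowSums(exp(S)))
      loss_hist[ep] <- mean(logZ - S[cbind(seq_len(n_pairs), centers)])
    } else {
      loss_hist[ep] <- ep_loss / n_pairs
    }
  }
  rownames(W_in) <- vocab
  structure(list(vectors = W_in, vocabulary = idx,
                 loss_history = loss_hist, config = cfg),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix>", nrow(x$vectors), "nodes x", ncol(x$vectors),
      "dims\n")
  invisible(x)
}

#' Look up node vectors, with a cold-start policy for unseen nodes
#'
#' @param emb An `embedding_matrix`.
#' @param ids Node IDs.
#' @param cold_start "zero" (default) assigns unseen nodes the zero vector;
#'   "mean" assigns the mean embedding. Either way a message reports them.
#' @return Matrix of vectors, one row per requested ID.
#' @export
embedding_vectors <- function(emb, ids, cold_start = c("zero", "mean")) {
  cold_start <- match.arg(cold_start)
  d <- ncol(emb$vectors)
  out <- matrix(0, length(ids), d, dimnames = list(ids, NULL))
  known <- ids %in% rownames(emb$vectors)
  if (any(known)) out[known, ] <- emb$vectors[ids[known], , drop = FALSE]
  if (any(!known)) {
    message(sum(!known), " node(s) absent from training walks; assigned ",
            cold_start, " vector")
    if (cold_start == "mean")
      out[!known, ] <- matrix(colMeans(emb$vectors), sum(!known), d,
                              byrow = TRUE)
  }
  out
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Cosine-similarity nearest neighbours of a node
#'
#' @param emb An `embedding_matrix`.
#' @param query_id Node ID present in the vocabulary.
#' @param k Number of neighbours (clipped to |V| - 1).
#' @return Data frame with columns `node_id`, `cosine`, sorted by descending
#'   cosine; ties broken by lexicographic node ID.
#' @export
most_similar <- function(emb, query_id, k = 10L) {
  stopifnot(k >= 1L)
  if (!query_id %in% rownames(emb$vectors))
    stop("unknown query node: ", query_id)
  q <- emb$vectors[query_id, ]
  others <- setdiff(rownames(emb$vectors), query_id)
  sims <- vapply(others, function(id) cosine_sim(q, emb$vectors[id, ]),
                 numeric(1))
  ord <- order(-sims, others)
  take <- ord[seq_len(min(k, length(others)))]
  data.frame(node_id = others[take], cosine = unname(sims[take]),
             stringsAsFactors = FALSE)
}

#' Write embeddings in word2vec text format
#'
#' First line "V dim", then one "id v1 ... vdim" line per node.
#' @param emb An `embedding_matrix`.
#' @param path Output path.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb$vectors), ncol(emb$vectors)), con)
  apply_lines <- vapply(rownames(emb$vectors), function(id)
    paste(id, paste(format(emb$vectors[id, ], digits = 17, trim = TRUE,
                           scientific = FALSE), collapse = " ")),
    character(1))
  writeLines(apply_lines, con)
  invisible(path)
}

#' Read embeddings in word2vec text format
#' @param path Path written by [write_embeddings()].
#' @return An `embedding_matrix` (without training history).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  vec <- t(vapply(parts, function(x) as.numeric(x[-1]), numeric(hdr[2])))
  rownames(vec) <- ids
  structure(list(vectors = vec,
                 vocabulary = stats::setNames(seq_along(ids), ids),
                 loss_history = numeric(0), config = NULL),
            class = "embedding_matrix")
}
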