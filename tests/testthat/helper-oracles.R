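# Independent naive reference implementations used as oracles. These are
# written directly from the formulas, loop-based, and share no code with
# the package internals they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

naive_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  for (i in seq_along(AA20)) out[i] <- sum(ch == AA20[i])
  out / length(ch)
}

naive_gaac <- function(seq) {
  groups <- list(c("G", "A", "V", "L", "M", "I"), c("F", "Y", "W"),
                 c("K", "R", "H"), c("D", "E"),
                 c("S", "T", "C", "P", "N", "Q"))
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(5)
  for (g in 1:5) for (r in groups[[g]]) out[g] <- out[g] + sum(ch == r)
  out / length(ch)
}

naive_ct_class <- function(res) {
  cls <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
              c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
              c("R", "K"), c("D", "E"), "C")
  for (k in 1:7) if (res %in% cls[[k]]) return(k)
  stop("unmapped residue")
}

naive_ct <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  f <- numeric(343)
  for (i in 1:(n - 2)) {
    a <- naive_ct_class(ch[i]); b <- naive_ct_class(ch[i + 1])
    c3 <- naive_ct_class(ch[i + 2])
    idx <- (a - 1) * 49 + (b - 1) * 7 + c3
    f[idx] <- f[idx] + 1
  }
  (f - min(f)) / max(f)
}

naive_qso <- function(seq, mats, w = 0.1, nlag = 30) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- numeric(0)
  for (m in mats) {
    tau <- numeric(nlag)
    for (d in 1:nlag) {
      s <- 0
      for (i in 1:(n - d)) s <- s + m[ch[i], ch[i + d]]^2
      tau[d] <- s
    }
    f <- numeric(20)
    for (r in seq_along(AA20)) f[r] <- sum(ch == AA20[r])
    denom <- sum(f) + w * sum(tau)
    out <- c(out, f / denom, w * tau / denom)
  }
  out
}

# exhaustive concordant-pair AUC (ties count 1/2)
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

clique_edges <- function(ids) t(combn(ids, 2))

mean_pairwise_cosine <- function(V, ids_a, ids_b = NULL) {
  cs <- function(a, b) sum(V[a, ] * V[b, ]) /
    sqrt(sum(V[a, ]^2) * sum(V[b, ]^2))
  if (is.null(ids_b)) {
    pr <- combn(ids_a, 2)
    return(mean(apply(pr, 2, function(p) cs(p[1], p[2]))))
  }
  mean(outer(ids_a, ids_b, Vectorize(cs)))
}

# separable pair-classification fixture: positives join two "sticky"
# proteins, negatives join two "inert" ones; linearly separable on the
# concatenated features
separable_pair_fixture <- function(n_prot = 60, n_pairs = 1000, d = 24,
                                   seed = 1) {
  set.seed(seed)
  sticky <- paste0("S", seq_len(n_prot / 2))
  inert <- paste0("I", seq_len(n_prot / 2))
  feats <- rbind(
    matrix(rnorm(length(sticky) * d, mean = 2), ncol = d,
           dimnames = list(sticky, NULL)),
    matrix(rnorm(length(inert) * d, mean = -2), ncol = d,
           dimnames = list(inert, NULL)))
  half <- n_pairs / 2
  pick2 <- function(pool) t(replicate(half, sample(pool, 2)))
  pos <- pick2(sticky); neg <- pick2(inert)
  pairs <- data.frame(id_m = c(pos[, 1], neg[, 1]),
                      id_n = c(pos[, 2], neg[, 2]),
                      label = rep(1:0, each = half),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, features = feats)
}

# well-separated multi-class blobs keyed by protein ID
blob_family_fixture <- function(n_classes = 5, per_class = 200, d = 24,
                                sep = 4, seed = 1) {
  set.seed(seed)
  ids <- character(0); fams <- character(0); rows <- list()
  for (k in seq_len(n_classes)) {
    center <- rnorm(d) * sep
    cls_ids <- sprintf("C%d_%03d", k, seq_len(per_class))
    rows[[k]] <- matrix(rnorm(per_class * d), ncol = d) +
      matrix(center, per_class, d, byrow = TRUE)
    ids <- c(ids, cls_ids)
    fams <- c(fams, rep(paste0("FAM", k), per_class))
  }
  feats <- do.call(rbind, rows)
  rownames(feats) <- ids
  list(examples = data.frame(id = ids, family = fams,
                             stringsAsFactors = FALSE),
       features = feats)
}
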