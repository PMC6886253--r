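# Balanced labelled dataset construction: subcellular-location-aware
# negative pair generation and the shuffled train/test split.

#' Read a location table (`id  location`, one row per id-location pair)
#'
#' @param path TSV path.
#' @return Named list mapping protein ID to its character vector of
#'   locations.
#' @export
read_location_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "location"),
                          colClasses = c("character", "character"))
  split(df$location, df$id)
}

#' @rdname read_location_table
#' @param locs Named list id -> locations.
#' @export
write_location_table <- function(locs, path) {
  df <- data.frame(id = rep(names(locs), lengths(locs)),
                   location = unlist(locs, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Generate location-disjoint negative pairs
#'
#' Rejection-samples random protein pairs until exactly `|positives|`
#' negatives are found (matching the equal positive/negative balance). A
#' pair qualifies only if the two proteins share no subcellular location,
#' is not a self-pair, does not duplicate a positive pair or another
#' negative (unordered).
#'
#' @param positives Data frame of positive pairs (`id_m`, `id_n`, optional
#'   `label`).
#' @param locations Named list id -> locations (see
#'   [read_location_table()]); must cover every candidate protein.
#' @param seed RNG seed.
#' @param candidates Protein IDs eligible for negatives (default: all
#'   proteins in `locations`).
#' @param max_tries Retry cap, as a multiple of the quota (default 1000).
#' @return Data frame `id_m`, `id_n`, `label = 0` with exactly
#'   `nrow(positives)` rows.
#' @export
generate_negatives <- function(positives, locations, seed = 1L,
                               candidates = names(locations),
                               max_tries = 1000L) {
  positives <- as.data.frame(positives)
  quota <- nrow(positives)
  stopifnot(quota >= 1L)
  uncovered <- setdiff(unique(c(positives$id_m, positives$id_n, candidates)),
                       names(locations))
  if (length(uncovered) > 0)
    stop("no location annotation for: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  set.seed(seed)
  taken <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pair_key(positives$id_m, positives$id_n)) assign(k, TRUE, taken)
  out_m <- character(quota); out_n <- character(quota)
  found <- 0L
  tries <- 0L
  cap <- max_tries * quota
  while (found < quota && tries < cap) {
    tries <- tries + 1L
    ab <- sample(candidates, 2L)
    if (length(intersect(locations[[ab[1]]], locations[[ab[2]]])) > 0) next
    k <- pair_key(ab[1], ab[2])
    if (exists(k, envir = taken, inherits = FALSE)) next
    assign(k, TRUE, taken)
    found <- found + 1L
    out_m[found] <- ab[1]; out_n[found] <- ab[2]
  }
  if (found < quota)
    stop("could only generate ", found, " of ", quota,
         " location-disjoint negative pairs; not enough cross-location ",
         "candidates")
  data.frame(id_m = out_m, id_n = out_n, label = 0L,
             stringsAsFactors = FALSE)
}

#' Independently verify a negative pair set
#'
#' @param negatives,positives Pair data frames.
#' @param locations Named list id -> locations.
#' @return TRUE invisibly; stops with a diagnosis on any violation
#'   (shared location, self-pair, overlap with positives, duplicate).
#' @export
verify_negatives <- function(negatives, positives, locations) {
  for (i in seq_len(nrow(negatives))) {
    a <- negatives$id_m[i]; b <- negatives$id_n[i]
    if (a == b) stop("self-pair at negative row ", i)
    if (length(intersect(locations[[a]], locations[[b]])) > 0)
      stop("negative pair (", a, ", ", b, ") shares a location")
  }
  nk <- pair_key(negatives$id_m, negatives$id_n)
  if (anyDuplicated(nk)) stop("duplicate negative pair")
  pk <- pair_key(positives$id_m, positives$id_n)
  if (any(nk %in% pk)) stop("negative duplicates a positive pair")
  invisible(TRUE)
}

#' Shuffle and split examples into train and test sets
#'
#' Rows are shuffled, then the first `floor(n * ratio)` go to train and the
#' remainder to test (80/20 under the default ratio).
#'
#' @param examples Data frame of examples.
#' @param ratio Train fraction in (0, 1) (default 0.8).
#' @param seed RNG seed.
#' @return List with `train` and `test` data frames (disjoint, union =
#'   input).
#' @export
split_dataset <- function(examples, ratio = 0.8, seed = 1L) {
  examples <- as.data.frame(examples)
  n <- nrow(examples)
  if (n < 2L) stop("need at least 2 examples to split")
  stopifnot(ratio > 0, ratio < 1)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(n * ratio)
  list(train = examples[ord[seq_len(n_train)], , drop = FALSE],
       test = examples[ord[-seq_len(n_train)], , drop = FALSE])
}

#' Build a balanced, shuffled, split PPI dataset
#'
#' Convenience driver: positives + location-disjoint negatives (equal
#' count), mixed and shuffled, split 80/20.
#'
#' @inheritParams generate_negatives
#' @param ratio Train fraction (default 0.8).
#' @return List with `train`, `test`, `negatives`.
#' @export
make_ppi_dataset <- function(positives, locations, ratio = 0.8, seed = 1L,
                             candidates = names(locations)) {
  positives <- as.data.frame(positives)
  if (is.null(positives$label)) positives$label <- 1L
  negatives <- generate_negatives(positives, locations, seed = seed,
                                  candidates = candidates)
  all_pairs <- rbind(positives[, c("id_m", "id_n", "label")], negatives)
  sp <- split_dataset(all_pairs, ratio = ratio, seed = seed + 1L)
  c(sp, list(negatives = negatives))
}
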