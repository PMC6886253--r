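# Undirected PPI network as a named adjacency list over opaque string IDs.

#' Construct a PPI network from an edge data frame
#'
#' Self-interactions are removed and duplicate (unordered) edges collapsed.
#'
#' @param edges Data frame or matrix with two ID columns.
#' @param isolated Optional character vector of additional degree-0 nodes.
#' @return A `ppi_network` with fields `nodes`, `edges` (two-column character
#'   matrix, lexicographically ordered pairs), `adjacency` (named list), and
#'   the `n_self_loops_removed` / `n_duplicates_removed` counts.
#' @export
ppi_network <- function(edges, isolated = character(0)) {
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(em) <- "character"
  em[] <- trimws(em)
  self <- em[, 1] == em[, 2]
  n_self <- sum(self)
  em <- em[!self, , drop = FALSE]
  # canonical unordered form
  flip <- em[, 1] > em[, 2]
  em[flip, ] <- em[flip, 2:1]
  key <- paste(em[, 1], em[, 2], sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  em <- em[!dup, , drop = FALSE]
  nodes <- sort(unique(c(as.vector(em), isolated)))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  if (nrow(em) > 0) {
    fwd <- split(em[, 2], factor(em[, 1], levels = nodes))
    rev <- split(em[, 1], factor(em[, 2], levels = nodes))
    for (v in nodes) adj[[v]] <- sort(c(fwd[[v]], rev[[v]]))
  }
  structure(list(nodes = nodes, edges = em, adjacency = adj,
                 n_self_loops_removed = n_self,
                 n_duplicates_removed = n_dup),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network>", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Load an undirected edge list from a TSV/whitespace file
#'
#' Two protein-ID columns per data line; lines starting with '#' are
#' skipped. Self-interactions are dropped and duplicate pairs collapsed,
#' with removal counts retained on the returned network.
#'
#' @param path Edge-list file.
#' @return A [ppi_network()].
#' @export
load_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty edge list: ", path)
    return(ppi_network(matrix(character(0), ncol = 2)))
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0)
    stop("malformed edge line ", bad[1], " in ", path, ": need two IDs")
  em <- t(vapply(parts, function(x) x[1:2], character(2)))
  ppi_network(em)
}

#' Write an edge list TSV
#' @param net A `ppi_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Metapath generation configuration
#'
#' @param length Walk length in nodes (default 10).
#' @param neighbor_size Contextual sampling fanout: walks started per node
#'   (default 4). With `per_step_sampling = TRUE` it instead bounds the
#'   candidate neighbours sampled at every step (alternative reading).
#' @param seed RNG seed.
#' @param per_step_sampling Alternative fanout interpretation (see above).
#' @return A `metapath_config` list.
#' @export
metapath_config <- function(length = 10L, neighbor_size = 4L, seed = 1L,
                            per_step_sampling = FALSE) {
  stopifnot(length >= 2L, neighbor_size >= 1L)
  structure(list(length = as.integer(length),
                 neighbor_size = as.integer(neighbor_size),
                 seed = as.integer(seed),
                 per_step_sampling = isTRUE(per_step_sampling)),
            class = "metapath_config")
}

#' Generate homogeneous metapaths by bounded random walks
#'
#' From every node, `neighbor_size` walks of `length` nodes are emitted;
#' each step moves to a uniformly sampled neighbour of the current node.
#' Isolated nodes yield length-1 walks (with a warning).
#'
#' @param net A [ppi_network()].
#' @param cfg A [metapath_config()].
#' @return List of character vectors (node-ID walks).
#' @export
generate_metapaths <- function(net, cfg = metapath_config()) {
  if (length(net$nodes) == 0L) stop("cannot walk an empty network")
  set.seed(cfg$seed)
  adj <- net$adjacency
  isolated <- names(adj)[vapply(adj, length, integer(1)) == 0L]
  if (length(isolated) > 0)
    warning(length(isolated), " isolated node(s) yield length-1 walks")
  walks <- vector("list", length(net$nodes) * cfg$neighbor_size)
  k <- 0L
  for (start in net$nodes) {
    for (r in seq_len(cfg$neighbor_size)) {
      walk <- character(cfg$length)
      walk[1] <- start
      cur <- start
      len <- 1L
      while (len < cfg$length) {
        nb <- adj[[cur]]
        if (length(nb) == 0L) break
        if (cfg$per_step_sampling && length(nb) > cfg$neighbor_size)
          nb <- sample(nb, cfg$neighbor_size)
        cur <- nb[sample.int(length(nb), 1L)]
        len <- len + 1L
        walk[len] <- cur
      }
      k <- k + 1L
      walks[[k]] <- walk[seq_len(len)]
    }
  }
  walks
}

#' Enumerate (center, context) records from walks
#'
#' For each position c in each walk, emits the center node together with the
#' nodes at offsets within `window`, clipped at walk ends.
#'
#' @param paths List of node-ID walks.
#' @param window Context radius (default 1).
#' @return List of lists with elements `center` and `contexts`.
#' @export
context_pairs <- function(paths, window = 1L) {
  stopifnot(window >= 1L)
  out <- list()
  for (p in paths) {
    L <- length(p)
    if (L < 2L) next
    for (c in seq_len(L)) {
      lo <- max(1L, c - window)
      hi <- min(L, c + window)
      ctx <- p[setdiff(lo:hi, c)]
      out[[length(out) + 1L]] <- list(center = p[c], contexts = ctx)
    }
  }
  out
}

#' Write walks in word2vec corpus dialect (one walk per line,
#' space-separated IDs)
#' @param walks List of walks.
#' @param path Output path.
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Read a walk corpus written by [write_walks()]
#' @param path Corpus path.
#' @return List of character-vector walks.
#' @export
read_walks <- function(path) {
  strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
}
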