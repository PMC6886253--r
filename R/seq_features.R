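#' @keywords internal
"_PACKAGE"

# Canonical 20-letter amino-acid alphabet, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default residue grouping for the grouped amino-acid composition
#'
#' Five physicochemical classes: aliphatic (g1), aromatic (g2), positively
#' charged (g3), negatively charged (g4) and uncharged polar (g5).
#'
#' @return Named list of character vectors partitioning the 20-letter
#'   alphabet.
#' @export
gaac_grouping <- function() {
  list(
    g1 = c("G", "A", "V", "L", "M", "I"),
    g2 = c("F", "Y", "W"),
    g3 = c("K", "R", "H"),
    g4 = c("D", "E"),
    g5 = c("S", "T", "C", "P", "N", "Q")
  )
}

#' Default conjoint-triad residue class map
#'
#' The standard seven conjoint-triad classes grouping residues by dipole and
#' side-chain volume: \{AGV\}, \{ILFP\}, \{YMTS\}, \{HNQW\}, \{RK\}, \{DE\},
#' \{C\}.
#'
#' @return Named integer vector mapping each residue to a class in 1..7.
#' @export
ct_classmap <- function() {
  classes <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                  c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                  c("R", "K"), c("D", "E"), c("C"))
  m <- integer(0)
  for (k in seq_along(classes)) {
    v <- rep(k, length(classes[[k]]))
    names(v) <- classes[[k]]
    m <- c(m, v)
  }
  m[AA_ALPHABET]
}

check_classmap <- function(classmap) {
  stopifnot(length(classmap) == 20L, !is.null(names(classmap)))
  classmap <- classmap[AA_ALPHABET]
  if (anyNA(classmap) || !all(classmap %in% 1:7))
    stop("conjoint-triad class map must assign every residue a class in 1..7")
  classmap
}

#' Construct a protein record
#'
#' Sanitizes the residue string according to `nonstandard`: non-canonical
#' residues (X, B, Z, U, O, ...) are dropped with a message (default),
#' rejected, or mapped to a stand-in canonical residue.
#'
#' @param id Identifier string.
#' @param sequence Amino-acid string (case-insensitive).
#' @param nonstandard One of "drop", "error", "map"; `map_to` gives the
#'   replacement residue when mapping.
#' @param map_to Canonical residue used when `nonstandard = "map"`.
#' @return An object of class `protein_record` with fields `id`, `sequence`.
#' @export
protein_record <- function(id, sequence, nonstandard = c("drop", "error", "map"),
                           map_to = "A") {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(gsub("[[:space:]*]", "", sequence))
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (nonstandard == "error")
      stop("non-canonical residues in ", id, ": ",
           paste(unique(chars[bad]), collapse = ","))
    if (nonstandard == "map") {
      stopifnot(map_to %in% AA_ALPHABET)
      chars[bad] <- map_to
    } else {
      message(sum(bad), " non-canonical residue(s) dropped from ", id)
      chars <- chars[!bad]
    }
  }
  if (length(chars) == 0L)
    stop("empty sequence for protein ", id)
  structure(list(id = id, sequence = paste(chars, collapse = "")),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "residues\n")
  invisible(x)
}

as_record <- function(p) {
  if (inherits(p, "protein_record")) return(p)
  if (is.character(p) && length(p) == 1L) return(protein_record("query", p))
  stop("expected a protein_record or a single sequence string")
}

residue_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  tab <- table(factor(chars, levels = AA_ALPHABET))
  as.numeric(tab)
}

#' Amino-acid composition descriptor (20 values)
#'
#' The fraction of each residue type, N(t)/N, in canonical alphabet order.
#'
#' @param p A `protein_record` (or plain sequence string).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
encode_aac <- function(p) {
  p <- as_record(p)
  n <- nchar(p$sequence)
  v <- residue_counts(p$sequence) / n
  names(v) <- paste0("AAC.", AA_ALPHABET)
  v
}

#' Grouped amino-acid composition descriptor (5 values)
#'
#' Frequency N_g/N of each of the five physicochemical residue groups.
#'
#' @inheritParams encode_aac
#' @param grouping Named list of residue classes partitioning the alphabet;
#'   see [gaac_grouping()].
#' @return Named numeric vector of length 5 summing to 1.
#' @export
encode_gaac <- function(p, grouping = gaac_grouping()) {
  p <- as_record(p)
  all_res <- sort(unlist(grouping, use.names = FALSE))
  if (!identical(all_res, AA_ALPHABET))
    stop("grouping must partition the 20-letter alphabet")
  counts <- residue_counts(p$sequence)
  names(counts) <- AA_ALPHABET
  v <- vapply(grouping, function(g) sum(counts[g]), numeric(1))
  v <- v / nchar(p$sequence)
  names(v) <- paste0("GAAC.", names(grouping))
  v
}

#' Conjoint-triad descriptor (343 values)
#'
#' Residues are mapped to 7 classes; every overlapping 3-residue window is a
#' triad, giving raw counts f_i over the 7^3 = 343 possible triads. Each
#' coordinate is normalized as d_i = (f_i - min f) / max f. Set
#' `conventional = TRUE` for the min-max form (f_i - min)/(max - min).
#'
#' @inheritParams encode_aac
#' @param classmap Named integer vector residue -> class 1..7; see
#'   [ct_classmap()].
#' @param conventional Use the (max - min) denominator instead of max.
#' @return Named numeric vector of length 343.
#' @export
encode_ct <- function(p, classmap = ct_classmap(), conventional = FALSE) {
  p <- as_record(p)
  classmap <- check_classmap(classmap)
  n <- nchar(p$sequence)
  if (n < 3L) stop("conjoint triad requires sequence length >= 3")
  cls <- classmap[strsplit(p$sequence, "")[[1]]]
  idx <- (cls[1:(n - 2)] - 1L) * 49L + (cls[2:(n - 1)] - 1L) * 7L + cls[3:n]
  f <- tabulate(idx, nbins = 343L)
  lo <- min(f); hi <- max(f)
  denom <- if (conventional) hi - lo else hi
  d <- if (denom > 0) (f - lo) / denom else rep(0, 343L)
  names(d) <- paste0("CT.", rep(1:7, each = 49), ".",
                     rep(rep(1:7, each = 7), 7), ".", rep(1:7, 49))
  d
}

load_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  m[AA_ALPHABET, AA_ALPHABET]
}

#' Default quasi-sequence-order distance matrices
#'
#' Two 20x20 residue-distance matrices: the Grantham (1974) matrix,
#' regenerated from its published composition/polarity/volume formula, and a
#' synthetic physicochemical matrix (z-scored Kyte-Doolittle hydrophobicity,
#' Hopp-Woods hydrophilicity and side-chain mass; RMS difference) standing in
#' for the Schneider-Wrede matrix, whose published values are not
#' redistributable here. Both are injectable via [qso_config()].
#'
#' @return Named list of two symmetric 20x20 matrices.
#' @export
qso_distance_matrices <- function() {
  list(
    physchem = load_distance_matrix(system.file(
      "extdata", "qso_physchem_synthetic_matrix.tsv", package = "ppimm")),
    grantham = load_distance_matrix(system.file(
      "extdata", "qso_grantham_matrix.tsv", package = "ppimm"))
  )
}

#' Quasi-sequence-order configuration
#'
#' @param w Weighting factor for the sequence-order coupling terms
#'   (dimensionless, default 0.1).
#' @param nlag Maximal lag for the coupling numbers tau_d (default 30).
#' @param distance_matrices Named list of one or two symmetric 20x20
#'   residue-distance matrices.
#' @param short_sequence "error" (default) rejects sequences with length
#'   <= nlag; "reduce" lowers nlag to length - 1 with a warning.
#' @return A `qso_config` list.
#' @export
qso_config <- function(w = 0.1, nlag = 30L,
                       distance_matrices = qso_distance_matrices(),
                       short_sequence = c("error", "reduce")) {
  stopifnot(w > 0, nlag >= 1L)
  for (m in distance_matrices) {
    stopifnot(is.matrix(m), all(dim(m) == c(20L, 20L)), all(m >= 0))
    if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  }
  structure(list(w = w, nlag = as.integer(nlag),
                 distance_matrices = distance_matrices,
                 short_sequence = match.arg(short_sequence)),
            class = "qso_config")
}

#' Quasi-sequence-order descriptor
#'
#' Per distance matrix: 20 composition descriptors
#' X_r = f_r / (sum f_r + w * sum tau_d) followed by nlag coupling
#' descriptors X_\{20+d\} = w * tau_d / (sum f_r + w * sum tau_d), where
#' tau_d = sum_i d(s_i, s_\{i+d\})^2 and f_r is the residue count. With the
#' two default matrices and nlag = 30 the block has 100 coordinates.
#'
#' @inheritParams encode_aac
#' @param cfg A [qso_config()].
#' @return Named numeric vector of length
#'   `length(matrices) * (20 + nlag)`.
#' @export
encode_qso <- function(p, cfg = qso_config()) {
  p <- as_record(p)
  chars <- strsplit(p$sequence, "")[[1]]
  n <- length(chars)
  nlag <- cfg$nlag
  if (n <= nlag) {
    if (cfg$short_sequence == "error")
      stop("sequence length ", n, " must exceed nlag = ", nlag,
           " for protein ", p$id)
    nlag <- n - 1L
    warning("nlag reduced to ", nlag, " for short sequence ", p$id)
  }
  f <- residue_counts(p$sequence)
  out <- numeric(0)
  for (mname in names(cfg$distance_matrices)) {
    m <- cfg$distance_matrices[[mname]]
    tau <- vapply(seq_len(nlag), function(d) {
      dd <- m[cbind(chars[1:(n - d)], chars[(1 + d):n])]
      sum(dd^2)
    }, numeric(1))
    denom <- sum(f) + cfg$w * sum(tau)
    block <- c(f / denom, cfg$w * tau / denom)
    names(block) <- paste0("QSO.", mname, ".",
                           c(AA_ALPHABET, paste0("tau", seq_len(nlag))))
    out <- c(out, block)
  }
  out
}

#' Full fixed-length descriptor vector (468 values by default)
#'
#' Concatenation [AAC(20) | GAAC(5) | CT(343) | QSO(100)] in fixed order.
#' Output length is determined solely by configuration, never by the
#' sequence.
#'
#' @inheritParams encode_aac
#' @param grouping Residue grouping for the GAAC block.
#' @param classmap Residue class map for the CT block.
#' @param qso A [qso_config()].
#' @param conventional_ct Passed to [encode_ct()].
#' @return Named numeric vector (468 under defaults).
#' @export
encode_all <- function(p, grouping = gaac_grouping(), classmap = ct_classmap(),
                       qso = qso_config(), conventional_ct = FALSE) {
  p <- as_record(p)
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, " encoding failed for ", p$id, ": ", conditionMessage(e),
           call. = FALSE))
  }
  c(wrap("AAC", encode_aac(p)),
    wrap("GAAC", encode_gaac(p, grouping)),
    wrap("CT", encode_ct(p, classmap, conventional_ct)),
    wrap("QSO", encode_qso(p, qso)))
}

#' Read a multi-record FASTA file of protein sequences
#'
#' Wrapped lines are handled; the record ID is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param ... Passed to [protein_record()] (residue sanitization policy).
#' @return List of `protein_record`s, named by ID.
#' @export
read_fasta <- function(path, ...) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  recs <- lapply(seq_along(set),
                 function(i) protein_record(ids[i], as.character(set[[i]]), ...))
  names(recs) <- ids
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records List of `protein_record`s.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Encode a set of proteins into a feature matrix
#'
#' @param records List of `protein_record`s (e.g. from [read_fasta()]).
#' @param descriptors Character subset of c("aac","gaac","ct","qso") in the
#'   fixed block order.
#' @inheritParams encode_all
#' @return Numeric matrix, one protein per row, block-labelled column names.
#' @export
encode_proteins <- function(records,
                            descriptors = c("aac", "gaac", "ct", "qso"),
                            grouping = gaac_grouping(),
                            classmap = ct_classmap(),
                            qso = qso_config(),
                            conventional_ct = FALSE) {
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  enc_one <- function(p) {
    out <- numeric(0)
    if ("aac" %in% descriptors) out <- c(out, encode_aac(p))
    if ("gaac" %in% descriptors) out <- c(out, encode_gaac(p, grouping))
    if ("ct" %in% descriptors) out <- c(out, encode_ct(p, classmap, conventional_ct))
    if ("qso" %in% descriptors) out <- c(out, encode_qso(p, qso))
    out
  }
  rows <- lapply(records, enc_one)
  mat <- do.call(rbind, rows)
  rownames(mat) <- unname(vapply(records, `[[`, character(1), "id"))
  mat
}

#' Write a feature matrix as TSV
#'
#' Header row carries the block-labelled column names; first column is the
#' protein ID. Deterministic column order.
#'
#' @param mat Matrix from [encode_proteins()].
#' @param path Output TSV path.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with protein IDs as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
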