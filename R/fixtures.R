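# Synthetic fixture generator: random protein sequences with per-family
# composition bias, planted-partition interaction graphs whose blocks carry
# disjoint subcellular locations, and coupled end-to-end bundles. Blocks
# double as the interaction signal and the family signal, so both
# supervised heads have learnable structure without external data.

LOCATION_NAMES <- c("Cytoplasm", "Nucleus", "Endoplasmic reticulum",
                    "Golgi apparatus", "Lysosome", "Mitochondrion",
                    "Cell membrane", "Lipid-anchor")

#' Synthetic fixture specification
#'
#' Defaults are the end-to-end acceptance fixture: 120 proteins in 2
#' planted blocks with within/between edge probabilities 0.3/0.02 and
#' sequence lengths 60-200 (always > the QSO nlag of 30).
#'
#' @param n_proteins Number of proteins (default 120).
#' @param length_range Sequence length bounds (default c(60, 200)).
#' @param n_blocks Planted communities (default 2).
#' @param p_in,p_out Within/between-block edge probabilities (defaults 0.3,
#'   0.02).
#' @param n_families Family labels; equal to `n_blocks` (default) or a
#'   multiple of it (each block split into subfamilies).
#' @param composition_shift Extra residue frequency mass concentrated on
#'   each family's preferred residues (default 0.1; 0 = uniform
#'   composition).
#' @param n_locations Distinct location labels, assigned block-disjointly
#'   (default `n_blocks`).
#' @param seed RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 120L, length_range = c(60L, 200L),
                         n_blocks = 2L, p_in = 0.3, p_out = 0.02,
                         n_families = n_blocks, composition_shift = 0.1,
                         n_locations = n_blocks, seed = 1L) {
  stopifnot(n_proteins >= n_blocks, length_range[1] >= 31L,
            length_range[2] >= length_range[1],
            p_out >= 0, p_out < p_in, p_in <= 1,
            n_families >= n_blocks, n_families %% n_blocks == 0L,
            composition_shift >= 0, composition_shift < 1,
                 n_locations >= n_blocks)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 n_families = as.integer(n_families),
                 composition_shift = composition_shift,
                 n_locations = as.integer(n_locations),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_ids <- function(spec)
  sprintf("SYN-%04dN", seq_len(spec$n_proteins))

fixture_blocks <- function(spec)
  stats::setNames(rep_len(seq_len(spec$n_blocks), spec$n_proteins),
                  fixture_ids(spec))

fixture_families <- function(spec) {
  blocks <- fixture_blocks(spec)
  per_block <- spec$n_families %/% spec$n_blocks
  fam <- character(length(blocks))
  for (b in seq_len(spec$n_blocks)) {
    members <- which(blocks == b)
    sub <- rep_len(seq_len(per_block), length(members))
    fam[members] <- sprintf("FAM%02d", (b - 1L) * per_block + sub)
  }
  stats::setNames(fam, names(blocks))
}

family_residue_freqs <- function(spec) {
  # each family biases a 5-residue subset by composition_shift extra mass
  base <- rep(1 / 20, 20)
  freqs <- matrix(base, spec$n_families, 20, byrow = TRUE)
  for (f in seq_len(spec$n_families)) {
    fav <- ((f - 1L) * 5L + 0:4) %% 20L + 1L
    freqs[f, fav] <- freqs[f, fav] + spec$composition_shift / 5
    freqs[f, ] <- freqs[f, ] / sum(freqs[f, ])
  }
  rownames(freqs) <- sort(unique(fixture_families(spec)))
  freqs
}

#' Generate random protein sequences with per-family composition bias
#'
#' Residues are drawn from a per-family multinomial (uniform plus
#' `composition_shift` extra mass on the family's preferred residues);
#' lengths are uniform in `length_range`.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of `protein_record`s.
#' @export
make_sequences <- function(spec) {
  set.seed(spec$seed)
  fams <- fixture_families(spec)
  freqs <- family_residue_freqs(spec)
  recs <- lapply(names(fams), function(id) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    seq <- paste(sample(AA_ALPHABET, len, replace = TRUE,
                        prob = freqs[fams[[id]], ]), collapse = "")
    protein_record(id, seq)
  })
  stats::setNames(recs, names(fams))
}

#' Generate a planted-partition PPI network with location and family tables
#'
#' Each unordered protein pair is an edge with probability `p_in` within a
#' block and `p_out` across blocks. Blocks are assigned disjoint
#' subcellular-location labels, so location-based negative sampling aligns
#' with cross-block non-edges.
#'
#' @param spec A [fixture_spec()].
#' @return List with `network` ([ppi_network()]), `locations` (named list),
#'   `families` (data frame id/family), `blocks` (named integer vector,
#'   ground truth).
#' @export
make_network <- function(spec) {
  set.seed(spec$seed + 1L)
  ids <- fixture_ids(spec)
  blocks <- fixture_blocks(spec)
  pairs <- utils::combn(ids, 2L)
  same <- blocks[pairs[1, ]] == blocks[pairs[2, ]]
  p <- ifelse(same, spec$p_in, spec$p_out)
  keep <- stats::runif(length(p)) < p
  em <- t(pairs[, keep, drop = FALSE])
  net <- ppi_network(em, isolated = ids)

  loc_labels <- if (spec$n_locations <= length(LOCATION_NAMES))
    LOCATION_NAMES[seq_len(spec$n_locations)]
  else paste0("LOC", seq_len(spec$n_locations))
  loc_per_block <- split(loc_labels,
                         rep_len(seq_len(spec$n_blocks), spec$n_locations))
  locations <- lapply(blocks, function(b) loc_per_block[[as.character(b)]])
  families <- data.frame(id = ids, family = unname(fixture_families(spec)),
                         stringsAsFactors = FALSE)
  list(network = net, locations = locations, families = families,
       blocks = blocks)
}

#' Generate a coupled end-to-end fixture bundle
#'
#' Composes [make_sequences()] and [make_network()]: every protein has a
#' sequence, a location set and a family; positive pairs are the sampled
#' edges. Byte-identical under a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `records`, `network`, `locations`, `families`,
#'   `positives` (pair data frame, label = 1), `blocks`, `spec`.
#' @export
make_end_to_end_fixture <- function(spec = fixture_spec()) {
  recs <- make_sequences(spec)
  net_part <- make_network(spec)
  edges <- net_part$network$edges
  positives <- data.frame(id_m = edges[, 1], id_n = edges[, 2], label = 1L,
                          stringsAsFactors = FALSE)
  c(list(records = recs), net_part, list(positives = positives, spec = spec))
}

#' Write a fixture bundle to a directory in the pipeline's file dialects
#'
#' Emits fasta, edge TSV, location TSV, family TSV and positive-pair TSV.
#'
#' @param bundle From [make_end_to_end_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "proteins.fasta"),
                edges = file.path(dir, "edges.tsv"),
                locations = file.path(dir, "locations.tsv"),
                families = file.path(dir, "families.tsv"),
                positives = file.path(dir, "positives.tsv"))
  write_fasta(bundle$records, paths$fasta)
  write_edge_list(bundle$network, paths$edges)
  write_location_table(bundle$locations, paths$locations)
  write_family_table(bundle$families, paths$families)
  write_pairs(bundle$positives, paths$positives)
  paths
}
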