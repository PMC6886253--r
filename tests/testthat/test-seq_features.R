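# Sequence descriptor encoders: examples, oracle equivalence, properties.

test_that("AAC matches the residue-fraction definition", {
  v <- encode_aac(protein_record("p", "AAAA"))
  expect_equal(unname(v[1]), 1.0)
  expect_equal(sum(v[-1]), 0)

  v <- encode_aac(protein_record("p", "ACDE"))
  expect_equal(unname(v[c("AAC.A", "AAC.C", "AAC.D", "AAC.E")]),
               rep(0.25, 4))
  expect_equal(sum(v), 1)

  set.seed(1)
  for (i in 1:10) {
    v <- encode_aac(protein_record("p", random_sequence(sample(5:300, 1))))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  expect_error(protein_record("p", ""), "empty")
})

test_that("GAAC matches the group-frequency definition", {
  expect_equal(unname(encode_gaac(protein_record("p", "GAVLMI"))),
               c(1, 0, 0, 0, 0))
  expect_equal(unname(encode_gaac(protein_record("p", "DE"))),
               c(0, 0, 0, 1, 0))
  expect_equal(unname(encode_gaac(protein_record("p", "FYWKRH"))),
               c(0, 0.5, 0.5, 0, 0))
  bad_grouping <- list(g1 = c("A", "C"), g2 = setdiff(LETTERS, c("A", "C")))
  expect_error(encode_gaac(protein_record("p", "ACDE"), bad_grouping),
               "partition")
})

test_that("conjoint triad has 343 coordinates normalized per definition", {
  v <- encode_ct(protein_record("p", random_sequence(40)))
  expect_length(v, 343)

  v <- encode_ct(protein_record("p", "AAAAA"))
  expect_equal(sum(v != 0), 1)
  expect_equal(max(v), 1.0)

  set.seed(2)
  v <- encode_ct(protein_record("p", random_sequence(25)))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(encode_ct(protein_record("p", "AC")), "length >= 3")
})

test_that("conventional min-max CT variant differs only by denominator", {
  set.seed(3)
  p <- protein_record("p", random_sequence(60))
  raw <- encode_ct(p)
  conv <- encode_ct(p, conventional = TRUE)
  # recover raw counts shape: both share min subtraction
  expect_true(all(conv >= raw - 1e-12))
  expect_equal(max(conv), 1.0)
})

test_that("QSO defaults and zero-coupling limit hold", {
  cfg <- qso_config()
  expect_equal(cfg$w, 0.1)
  expect_equal(cfg$nlag, 30L)
  expect_length(cfg$distance_matrices, 2L)

  # homopolymer + zero diagonal: all tau_d = 0 so X_r = f_r / sum f_r
  v <- encode_qso(protein_record("p", strrep("A", 50)), cfg)
  expect_equal(unname(v[c(1, 21 + 30)]), c(1, 1))  # A fraction per matrix
  expect_equal(sum(v[21:50]), 0)                   # coupling block zero

  expect_error(encode_qso(protein_record("p", random_sequence(20)), cfg),
               "exceed nlag")
  cfg_reduce <- qso_config(short_sequence = "reduce")
  expect_warning(v2 <- encode_qso(protein_record("p", random_sequence(20)),
                                  cfg_reduce), "nlag reduced")
  expect_length(v2, 2 * (20 + 19))
})

test_that("each encoder matches its independent naive oracle", {
  set.seed(4)
  cfg <- qso_config()
  for (i in 1:100) {
    seq <- random_sequence(sample(31:150, 1))
    p <- protein_record("p", seq)
    expect_equal(unname(encode_aac(p)), naive_aac(seq), tolerance = 1e-10)
    expect_equal(unname(encode_gaac(p)), naive_gaac(seq), tolerance = 1e-10)
    expect_equal(unname(encode_ct(p)), naive_ct(seq), tolerance = 1e-10)
    expect_equal(unname(encode_qso(p, cfg)),
                 naive_qso(seq, cfg$distance_matrices), tolerance = 1e-10)
  }
})

test_that("full concatenation is configuration-determined at length 468", {
  set.seed(5)
  lens <- sample(31:2000, 1000, replace = TRUE)
  widths <- vapply(lens, function(len)
    length(encode_all(protein_record("p", random_sequence(len)))),
    integer(1))
  expect_true(all(widths == 468L))

  p <- protein_record("p", random_sequence(80))
  v <- encode_all(p)
  expect_length(v, 468)
  expect_equal(sum(v[1:20]), 1, tolerance = 1e-12)
  expect_equal(sum(v[21:25]), 1, tolerance = 1e-12)
  expect_identical(v, encode_all(protein_record("p", p$sequence)))
  # sub-encoder failures are annotated
  expect_error(encode_all(protein_record("p", random_sequence(25))), "QSO")
})

test_that("AAC/GAAC are permutation-invariant, CT/QSO are not", {
  set.seed(6)
  seq <- random_sequence(60)
  shuffled <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  a <- protein_record("a", seq); b <- protein_record("b", shuffled)
  expect_equal(unname(encode_aac(a)), unname(encode_aac(b)))
  expect_equal(unname(encode_gaac(a)), unname(encode_gaac(b)))
  expect_false(isTRUE(all.equal(unname(encode_ct(a)), unname(encode_ct(b)))))
  expect_false(isTRUE(all.equal(unname(encode_qso(a)), unname(encode_qso(b)))))
})

test_that("non-canonical residue policies work", {
  expect_message(p <- protein_record("p", "ACDXZE"), "dropped")
  expect_equal(p$sequence, "ACDE")
  expect_error(protein_record("p", "ACDX", nonstandard = "error"),
               "non-canonical")
  p2 <- protein_record("p", "ACDX", nonstandard = "map", map_to = "G")
  expect_equal(p2$sequence, "ACDG")
})

test_that("FASTA and feature-matrix round trips preserve content", {
  set.seed(7)
  recs <- lapply(1:5, function(i)
    protein_record(paste0("prot", i), random_sequence(120)))
  names(recs) <- vapply(recs, `[[`, "", "id")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_identical(names(back), names(recs))
  expect_identical(vapply(back, `[[`, "", "sequence"),
                   vapply(recs, `[[`, "", "sequence"))

  mat <- encode_proteins(recs)
  expect_equal(dim(mat), c(5L, 468L))
  tsv <- tempfile(fileext = ".tsv")
  write_feature_matrix(mat, tsv)
  expect_equal(read_feature_matrix(tsv), mat, tolerance = 1e-12)

  # descriptor subsetting drives the width
  expect_equal(ncol(encode_proteins(recs, descriptors = c("aac", "gaac"))),
               25L)
})
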