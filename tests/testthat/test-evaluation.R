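# Metrics and cross-validation.

test_that("binary metrics evaluate the defining ratios exactly", {
  m <- binary_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(m[c("precision", "accuracy", "specificity",
                          "recall")]), rep(1, 4), ignore_attr = TRUE)

  m <- binary_metrics(list(TP = 90, FP = 10, TN = 80, FN = 20))
  expect_equal(m$precision, 0.9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$specificity, 80 / 90)
  expect_equal(m$recall, 90 / 110)
  expect_equal(m$f1, 2 * 0.9 * (90 / 110) / (0.9 + 90 / 110))

  m <- binary_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_true(is.na(m$precision))
  expect_true("precision" %in% m$undefined)

  expect_error(binary_metrics(list(TP = -1, FP = 0, TN = 0, FN = 2)),
               "negative")
})

test_that("accuracy is invariant under label swap", {
  set.seed(1)
  for (i in 1:20) {
    counts <- as.list(stats::setNames(sample(0:30, 4, TRUE),
                                      c("TP", "FP", "TN", "FN")))
    if (sum(unlist(counts)) == 0) next
    swapped <- list(TP = counts$TN, FP = counts$FN, TN = counts$TP,
                    FN = counts$FP)
    expect_equal(binary_metrics(counts)$accuracy,
                 binary_metrics(swapped)$accuracy)
  }
})

test_that("AUC matches trivial cases and the 4-point toy set", {
  expect_equal(auc_roc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  expect_equal(auc_roc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_equal(auc_roc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.3)), 0.75)
  expect_error(auc_roc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC equals the exhaustive concordant-pair oracle (n <= 12)", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)  # ties likely
    expect_equal(auc_roc(labels, scores), brute_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("F1 averaging follows the micro/macro definitions", {
  lab <- c("a", "a", "b", "b", "c")
  expect_equal(f1_scores(lab, lab, "micro"), 1.0)
  expect_equal(f1_scores(lab, lab, "macro"), 1.0)

  # 3-class toy table, hand-computed per-class F1
  truth <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "b", "a", "b", "c", "c")
  # a: TP2 FP0 FN1 -> F1 = 4/5; b: TP1 FP1 FN1 -> F1 = 1/2
  # c: TP1 FP1 FN0 -> F1 = 2/3
  expect_equal(f1_scores(truth, pred, "macro"), (4 / 5 + 1 / 2 + 2 / 3) / 3,
               tolerance = 1e-12)
  # micro: P = R = 4/6
  expect_equal(f1_scores(truth, pred, "micro"), 4 / 6, tolerance = 1e-12)

  expect_error(f1_scores(character(0), character(0)), "empty")
})

test_that("stratified cross-validation partitions and is deterministic", {
  labels <- rep(0:1, each = 50)
  folds <- stratified_folds(labels, k = 5, seed = 1)
  expect_equal(as.vector(table(folds)), rep(20L, 5))
  # stratification: each fold has 10 of each class
  for (f in 1:5) expect_equal(sum(labels[folds == f]), 10L)
  expect_identical(folds, stratified_folds(labels, k = 5, seed = 1))
  expect_error(stratified_folds(c(rep(0, 30), 1, 1), k = 5), "fewer than k")

  set.seed(3)
  scores_all <- stats::runif(100) * 0.5 + labels * 0.4
  rep1 <- cross_validate(labels, function(tr, te) scores_all[te],
                         k = 5, seed = 2, task = "ppi")
  expect_equal(nrow(rep1$folds), 5L)
  expect_equal(unname(rep1$mean["accuracy"]),
               mean(rep1$folds$accuracy), tolerance = 1e-12)
  rep2 <- cross_validate(labels, function(tr, te) scores_all[te],
                         k = 5, seed = 2, task = "ppi")
  expect_identical(rep1$folds, rep2$folds)

  # family task wiring
  fam <- rep(c("x", "y", "z"), each = 12)
  repf <- cross_validate(fam, function(tr, te) fam[te], k = 3, seed = 1,
                         task = "family")
  expect_equal(unname(repf$mean["micro_f1"]), 1.0)
})

test_that("reports serialize to JSON and TSV", {
  labels <- rep(0:1, each = 10)
  rep1 <- cross_validate(labels, function(tr, te) as.numeric(labels[te]),
                         k = 2, seed = 1, task = "ppi")
  fj <- tempfile(fileext = ".json"); ft <- tempfile(fileext = ".tsv")
  write_metric_report(rep1, fj, ft)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$mean$accuracy, 1.0)
  expect_equal(nrow(utils::read.table(ft, header = TRUE)), 2L)

  pts <- roc_points(labels, seq(0, 1, length.out = 20))
  expect_equal(pts$tpr[1], 0)
  expect_equal(utils::tail(pts$tpr, 1), 1)
})
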