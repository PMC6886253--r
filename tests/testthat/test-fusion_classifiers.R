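# Late fusion and the two supervised heads.

test_that("fusion concatenates with width conservation", {
  topo <- rnorm(128); seqf <- rnorm(64)
  u <- fuse_features(topo, seqf)
  expect_length(u, 192L)
  expect_equal(u[1:128], topo)

  expect_equal(fuse_features(numeric(128), numeric(64)), numeric(192))

  # arbitrary configured dims, not just defaults
  for (dims in list(c(16, 8), c(5, 11), c(300, 1))) {
    u <- fuse_features(rnorm(dims[1]), rnorm(dims[2]))
    expect_length(u, sum(dims))
  }

  A <- matrix(1:6, 2); B <- matrix(7:14, 2)
  expect_equal(dim(fuse_features(A, B)), c(2L, 7L))
  expect_error(fuse_features(matrix(1, 2, 2), matrix(1, 3, 2)), "mismatch")
})

test_that("cross-entropy losses match hand-computed values", {
  # balanced set at yhat = 0.5 gives ln 2
  expect_equal(bce_loss(c(1, 0, 1, 0), rep(0.5, 4)), log(2),
               tolerance = 1e-12)

  # 3-example toy batch, by hand
  y <- c(1, 0, 1); yhat <- c(0.9, 0.2, 0.6)
  by_hand <- -(log(0.9) + log(0.8) + log(0.6)) / 3
  expect_equal(bce_loss(y, yhat), by_hand, tolerance = 1e-10)

  P <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.25, 0.25, 0.5))
  lab <- c(1L, 2L, 3L)
  by_hand <- -(log(0.7) + log(0.8) + log(0.5)) / 3
  expect_equal(cce_loss(lab, P), by_hand, tolerance = 1e-10)
  Y <- diag(3)
  expect_equal(cce_loss(Y, P), by_hand, tolerance = 1e-10)

  # one-hot-correct predictor scores (near) zero loss; clipping bounds it
  expect_lt(cce_loss(lab, diag(3)), 1e-6)
})

test_that("interaction head separates a verified separable fixture", {
  fx <- separable_pair_fixture(seed = 11)
  sp <- split_dataset(fx$pairs, ratio = 0.8, seed = 1)

  # pre-verify separability with a linear baseline on concatenated feats
  tr <- sp$train
  Xtr <- cbind(fx$features[tr$id_m, ], fx$features[tr$id_n, ])
  # perfect separation warnings are expected here: separability is the point
  lin <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), tr$label,
                                         family = stats::binomial()))
  Xte <- cbind(1, cbind(fx$features[sp$test$id_m, ],
                        fx$features[sp$test$id_n, ]))
  lin_acc <- mean((plogis(Xte %*% lin$coefficients) >= 0.5) == sp$test$label)
  expect_gt(lin_acc, 0.95)

  model <- train_ppi_classifier(tr, fx$features,
                                ppi_classifier_config(epochs = 60L, seed = 2L))
  scores <- predict_interaction(model,
                                fx$features[sp$test$id_m, , drop = FALSE],
                                fx$features[sp$test$id_n, , drop = FALSE])
  expect_true(all(scores >= 0 & scores <= 1))
  acc <- mean((scores >= 0.5) == sp$test$label)
  expect_gt(acc, 0.95)
  expect_gt(auc_roc(sp$test$label, scores), 0.95)

  # deterministic prediction and pair-order symmetry (augmented training)
  m1 <- fx$features[sp$test$id_m[1], ]; n1 <- fx$features[sp$test$id_n[1], ]
  expect_identical(predict_interaction(model, m1, n1),
                   predict_interaction(model, m1, n1))
  expect_equal(predict_interaction(model, m1, n1),
               predict_interaction(model, n1, m1), tolerance = 1e-12)
})

test_that("interaction head rejects bad inputs", {
  fx <- separable_pair_fixture(n_pairs = 20, seed = 3)
  ones <- fx$pairs[fx$pairs$label == 1, ]
  expect_error(train_ppi_classifier(ones, fx$features), "both")
  bad <- fx$pairs; bad$id_m[1] <- "missing_protein"
  expect_error(train_ppi_classifier(bad, fx$features), "missing_protein")
  expect_error(predict_interaction(list(), rnorm(3), rnorm(3)), "ppi_model")
  model <- train_ppi_classifier(fx$pairs, fx$features,
                                ppi_classifier_config(epochs = 2L))
  expect_error(predict_interaction(model, rnorm(3), rnorm(3)), "width")
})

test_that("family head classifies well-separated blobs", {
  fx <- blob_family_fixture(n_classes = 5, per_class = 200, seed = 5)
  sp <- split_dataset(fx$examples, ratio = 0.8, seed = 2)
  model <- train_family_classifier(sp$train, fx$features,
                                   family_classifier_config(epochs = 60L,
                                                            seed = 3L))
  pred <- predict_family(model, fx$features[sp$test$id, , drop = FALSE])
  expect_equal(unname(rowSums(pred$prob)), rep(1, nrow(sp$test)),
               tolerance = 1e-6)
  expect_gt(f1_scores(sp$test$family, pred$label, "micro"), 0.9)
})

test_that("family head enforces class prerequisites", {
  fx <- blob_family_fixture(n_classes = 2, per_class = 5, seed = 6)
  one_class <- fx$examples[fx$examples$family == "FAM1", ]
  expect_error(train_family_classifier(one_class, fx$features), "2 family")
  singleton <- rbind(fx$examples[fx$examples$family == "FAM1", ],
                     fx$examples[fx$examples$family == "FAM2", ][1, ])
  expect_error(train_family_classifier(singleton, fx$features),
               "filter_families")
})

test_that("both heads can memorize a 50-example fixture", {
  set.seed(7)
  feats <- matrix(rnorm(20 * 16), 20, 16,
                  dimnames = list(paste0("P", 1:20), NULL))
  pairs <- data.frame(id_m = sample(rownames(feats), 50, TRUE),
                      id_n = sample(rownames(feats), 50, TRUE))
  pairs <- pairs[pairs$id_m != pairs$id_n, ][1:40, ]
  pairs$label <- rep(0:1, 20)
  pm <- train_ppi_classifier(pairs, feats,
                             ppi_classifier_config(epochs = 400L, seed = 1L,
                                                   symmetrize = FALSE))
  scores <- predict_interaction(pm, feats[pairs$id_m, ], feats[pairs$id_n, ])
  expect_gte(mean((scores >= 0.5) == pairs$label), 0.98)

  fam <- data.frame(id = rownames(feats),
                    family = rep(c("X", "Y"), each = 10))
  fm <- train_family_classifier(fam, feats,
                                family_classifier_config(epochs = 400L,
                                                         dropout = 0,
                                                         seed = 1L))
  expect_gte(mean(predict_family(fm, feats)$label == fam$family), 0.98)
})

test_that("family filtering keeps strictly-larger-than-min families", {
  ex <- data.frame(id = sprintf("p%02d", 1:34),
                   family = rep(c("big", "edge", "tiny"), c(16, 15, 3)))
  out <- filter_families(ex, 15)
  expect_equal(out$families, "big")
  expect_equal(nrow(out$examples), 16L)

  expect_equal(filter_families(ex, 0)$examples, ex)

  out2 <- filter_families(ex, 10)
  expect_equal(nrow(out2$examples),
               sum(table(ex$family)[out2$families]), ignore_attr = TRUE)
})

test_that("pair and family tables round-trip as TSV", {
  pairs <- data.frame(id_m = c("a", "b"), id_n = c("c", "d"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  f <- tempfile()
  write_pairs(pairs, f)
  expect_equal(read_pairs(f), pairs)
  fam <- data.frame(id = c("a", "b"), family = c("F1", "F2"),
                    stringsAsFactors = FALSE)
  write_family_table(fam, f)
  expect_equal(read_family_table(f), fam)
})
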