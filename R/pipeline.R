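# End-to-end pipeline driver: encode -> walks -> embed -> sae -> fuse ->
# train/predict -> evaluate, with per-stage seeds derived from one master
# seed and a manifest of every artifact written.

#' Pipeline configuration with the published hyper-parameter defaults
#'
#' Batch size 64, learning rate 0.01, SAE architecture 256-128-64-128-256,
#' plain SGD, CBOW window 1 and embedding size 128, walk fanout 4 and
#' length 10, CBOW/SAE/DNN epochs 10/50/200, dropout 0.5, QSO weight 0.1
#' and nlag 30, 80/20 split, family min-count 15. Any override is logged.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    batch_size = 64L, learning_rate = 0.01,
    sae_layers = c(256L, 128L, 64L, 128L, 256L),
    window = 1L, embedding_dim = 128L,
    neighbor_size = 4L, walk_length = 10L,
    cbow_epochs = 10L, sae_epochs = 50L, dnn_epochs = 200L,
    dropout = 0.5, qso_w = 0.1, qso_nlag = 30L,
    split_ratio = 0.8, family_min_count = 15L,
    cbow_mode = "negative", seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  if (length(overrides) > 0)
    message("pipeline config overrides: ",
            paste(names(overrides), collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  int_fields <- c("batch_size", "window", "embedding_dim", "neighbor_size",
                  "walk_length", "cbow_epochs", "sae_epochs", "dnn_epochs",
                  "qso_nlag", "family_min_count", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$sae_layers <- as.integer(cfg$sae_layers)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as JSON
#'
#' @param path JSON path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

# per-stage seeds derived from the master seed; kept well below 2^31
stage_seed <- function(config, stage) {
  offsets <- c(walks = 1L, cbow = 2L, sae = 3L, split = 4L, negatives = 5L,
               ppi = 6L, family = 7L, fixture = 8L)
  (config$seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Run the full multimodal pipeline on file inputs
#'
#' Stages: descriptor encoding; balanced dataset construction (negatives +
#' 80/20 split); metapath walks over the training-split interactions only
#' (test edges are held out of walk generation); CBOW embedding; SAE deep
#' features; late fusion; twin-branch interaction training and held-out
#' evaluation; optional family filtering, training and evaluation. Every
#' intermediate is written to `out_dir` along with `manifest.json` (file
#' MD5 hashes) and the resolved configuration.
#'
#' @param inputs Named list of paths: `fasta`, `edges`, `locations`
#'   (optional if `pairs_train`/`pairs_test` supplied), `families`
#'   (optional).
#' @param out_dir Artifact directory (created).
#' @param config A [pipeline_config()].
#' @return Invisible list with the trained models, the metric reports and
#'   the artifact paths.
#' @export
run_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(out_dir, "config.json"))
  write_pipeline_config(config, paths$config)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  records <- stage("encode", read_fasta(inputs$fasta))
  qso <- qso_config(w = config$qso_w, nlag = config$qso_nlag)
  features <- stage("encode", encode_proteins(records, qso = qso))
  paths$features <- file.path(out_dir, "features.tsv")
  write_feature_matrix(features, paths$features)

  net <- stage("dataset", load_edge_list(inputs$edges))
  positives <- data.frame(id_m = net$edges[, 1], id_n = net$edges[, 2],
                          label = 1L, stringsAsFactors = FALSE)
  locations <- stage("dataset", read_location_table(inputs$locations))
  ds <- stage("dataset", {
    negatives <- generate_negatives(positives, locations,
                                    seed = stage_seed(config, "negatives"),
                                    candidates = intersect(names(locations),
                                                           rownames(features)))
    all_pairs <- rbind(positives, negatives)
    sp <- split_dataset(all_pairs, ratio = config$split_ratio,
                        seed = stage_seed(config, "split"))
    c(sp, list(negatives = negatives))
  })
  paths$pairs_train <- file.path(out_dir, "pairs_train.tsv")
  paths$pairs_test <- file.path(out_dir, "pairs_test.tsv")
  write_pairs(ds$train, paths$pairs_train)
  write_pairs(ds$test, paths$pairs_test)

  walks <- stage("walks", {
    train_pos <- ds$train[ds$train$label == 1L, ]
    walk_net <- ppi_network(cbind(train_pos$id_m, train_pos$id_n),
                            isolated = rownames(features))
    generate_metapaths(walk_net,
                       metapath_config(length = config$walk_length,
                                       neighbor_size = config$neighbor_size,
                                       seed = stage_seed(config, "walks")))
  })
  paths$walks <- file.path(out_dir, "walks.txt")
  write_walks(walks, paths$walks)

  emb <- stage("embed", train_cbow(walks, cbow_config(
    dim = config$embedding_dim, window = config$window,
    epochs = config$cbow_epochs, seed = stage_seed(config, "cbow"),
    softmax_mode = config$cbow_mode)))
  paths$embeddings <- file.path(out_dir, "embeddings.txt")
  write_embeddings(emb, paths$embeddings)

  sae <- stage("sae", train_sae(features, sae_config(
    layer_sizes = config$sae_layers, epochs = config$sae_epochs,
    batch_size = config$batch_size, learning_rate = config$learning_rate,
    seed = stage_seed(config, "sae"))))
  paths$sae <- file.path(out_dir, "sae_model.json")
  write_sae(sae, paths$sae)
  paths$sae_history <- file.path(out_dir, "sae_history.csv")
  utils::write.csv(sae$history, paths$sae_history, row.names = FALSE)

  fused <- stage("fuse", fused_matrix(emb, sae, features))
  paths$fused <- file.path(out_dir, "fused.tsv")
  write_feature_matrix(fused, paths$fused)

  ppi_model <- stage("train-ppi", train_ppi_classifier(
    ds$train, fused, ppi_classifier_config(
      epochs = config$dnn_epochs, batch_size = config$batch_size,
      learning_rate = config$learning_rate,
      seed = stage_seed(config, "ppi"))))
  ppi_report <- stage("evaluate-ppi", {
    scores <- predict_interaction(ppi_model,
                                  fused[ds$test$id_m, , drop = FALSE],
                                  fused[ds$test$id_n, , drop = FALSE])
    truth <- ds$test$label
    m <- binary_metrics(confusion_counts(truth, as.integer(scores >= 0.5)))
    m$auc_roc <- auc_roc(truth, scores)
    paths$ppi_predictions <- file.path(out_dir, "ppi_predictions.tsv")
    utils::write.table(data.frame(ds$test$id_m, ds$test$id_n, scores),
                       paths$ppi_predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    m
  })

  family_model <- NULL
  family_report <- NULL
  if (!is.null(inputs$families)) {
    fam <- stage("train-family", {
      fam_all <- read_family_table(inputs$families)
      filt <- filter_families(fam_all, config$family_min_count)
      if (nrow(filt$examples) == 0L)
        stop("no family exceeds min_count = ", config$family_min_count)
      filt
    })
    fam_split <- split_dataset(fam$examples, ratio = config$split_ratio,
                               seed = stage_seed(config, "split"))
    family_model <- stage("train-family", train_family_classifier(
      fam_split$train, fused, family_classifier_config(
        epochs = config$dnn_epochs, batch_size = config$batch_size,
        learning_rate = config$learning_rate, dropout = config$dropout,
        seed = stage_seed(config, "family"))))
    family_report <- stage("evaluate-family", {
      pred <- predict_family(family_model,
                             fused[fam_split$test$id, , drop = FALSE])
      truth <- fam_split$test$family
      list(accuracy = mean(pred$label == truth),
           micro_f1 = f1_scores(truth, pred$label, "micro"),
           macro_f1 = f1_scores(truth, pred$label, "macro"))
    })
  }

  metrics <- list(ppi = ppi_report, family = family_report)
  paths$metrics <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, paths$metrics, digits = NA,
                       auto_unbox = TRUE, na = "null")

  files <- unlist(paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)

  invisible(list(config = config, features = features, embedding = emb,
                 sae = sae, fused = fused, ppi_model = ppi_model,
                 family_model = family_model, metrics = metrics,
                 paths = paths))
}
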