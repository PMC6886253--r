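# Evaluation metrics and the stratified k-fold cross-validation driver.

#' Confusion counts from hard binary predictions
#'
#' @param labels 0/1 truth.
#' @param predictions 0/1 predictions.
#' @return A `confusion_counts` list with TP, FP, TN, FN.
#' @export
confusion_counts <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions),
            all(labels %in% 0:1), all(predictions %in% 0:1))
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 FP = sum(labels == 0 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FN = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' Precision = TP/(TP+FP), ACC = (TP+TN)/n, SPC = TN/(TN+FP),
#' Recall = TP/(TP+FN), F1 = 2PR/(P+R). A metric whose denominator is zero
#' is reported as NA with its name listed in `undefined` (never silently
#' 0).
#'
#' @param c A [confusion_counts()] (or list with TP, FP, TN, FN).
#' @return List with precision, accuracy, specificity, recall, f1,
#'   `undefined` (character vector).
#' @export
binary_metrics <- function(c) {
  with(c, {
    if (any(c(TP, FP, TN, FN) < 0)) stop("negative confusion counts")
    n <- TP + FP + TN + FN
    if (n < 1) stop("empty confusion table")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    precision <- ratio(TP, TP + FP)
    recall <- ratio(TP, TP + FN)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    res <- list(precision = precision,
                accuracy = (TP + TN) / n,
                specificity = ratio(TN, TN + FP),
                recall = recall,
                f1 = f1)
    res$undefined <- names(res)[vapply(res, function(x)
      is.numeric(x) && is.na(x), logical(1))]
    res
  })
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation, equivalent to trapezoidal integration
#' over all thresholds with ties contributing 1/2.
#'
#' @param labels 0/1 truth (both classes required).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0,1\].
#' @export
auc_roc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points for plotting/export
#'
#' @inheritParams auc_roc
#' @return Data frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the endpoints.
#' @export
roc_points <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Micro- or macro-averaged F1 for multi-class predictions
#'
#' Micro pools TP/FP/FN globally; macro averages per-class F1 without
#' weights, with classes absent from the predictions contributing 0.
#'
#' @param labels True class labels (factor or character).
#' @param predictions Predicted class labels.
#' @param averaging "micro" or "macro".
#' @return F1 value in \[0,1\].
#' @export
f1_scores <- function(labels, predictions, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(predictions))
  labels <- as.character(labels); predictions <- as.character(predictions)
  classes <- sort(unique(c(labels, predictions)))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(labels == cl & predictions == cl)
    fp[cl] <- sum(labels != cl & predictions == cl)
    fn[cl] <- sum(labels == cl & predictions != cl)
  }
  if (averaging == "micro") {
    p <- sum(tp) / (sum(tp) + sum(fp))
    r <- sum(tp) / (sum(tp) + sum(fn))
    if (p + r == 0) return(0)
    return(2 * p * r / (p + r))
  }
  per_class <- vapply(classes, function(cl) {
    denom <- 2 * tp[cl] + fp[cl] + fn[cl]
    if (denom == 0) 0 else 2 * tp[cl] / denom
  }, numeric(1))
  mean(per_class)
}

#' Stratified k-fold assignment
#'
#' @param labels Class labels (binary or multi-class).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold IDs in 1..k, one per example, with class
#'   proportions preserved per fold.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  stopifnot(k >= 2L, n >= k)
  counts <- table(as.character(labels))
  if (any(counts < k))
    stop("class '", names(counts)[which.min(counts)], "' has fewer than k = ",
         k, " examples; cannot stratify")
  set.seed(seed)
  folds <- integer(n)
  for (cl in names(counts)) {
    idx <- sample(which(as.character(labels) == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation driver
#'
#' For each fold, calls `fit_predict(train_idx, test_idx)` which must
#' return either numeric scores (binary task: AUC + thresholded metrics are
#' computed) or class labels (multi-class: micro/macro F1 + accuracy).
#'
#' @param labels Truth labels (0/1 for the binary task).
#' @param fit_predict Function(train_idx, test_idx) -> predictions for
#'   `test_idx`.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param task "ppi" (binary, scores) or "family" (multi-class, labels).
#' @return A `metric_report`: list with `folds` (per-fold data frame),
#'   `mean`, `sd`.
#' @export
cross_validate <- function(labels, fit_predict, k = 5L, seed = 1L,
                           task = c("ppi", "family")) {
  task <- match.arg(task)
  folds <- stratified_folds(labels, k = k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    pred <- fit_predict(train_idx, test_idx)
    truth <- labels[test_idx]
    if (task == "ppi") {
      scores <- as.numeric(pred)
      m <- binary_metrics(confusion_counts(truth, as.integer(scores >= 0.5)))
      rows[[f]] <- data.frame(fold = f, precision = m$precision,
                              accuracy = m$accuracy,
                              specificity = m$specificity,
                              recall = m$recall, f1 = m$f1,
                              auc_roc = auc_roc(truth, scores))
    } else {
      rows[[f]] <- data.frame(fold = f,
                              accuracy = mean(as.character(pred) ==
                                                as.character(truth)),
                              micro_f1 = f1_scores(truth, pred, "micro"),
                              macro_f1 = f1_scores(truth, pred, "macro"))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(folds = per_fold,
                 mean = colMeans(per_fold[metric_cols], na.rm = TRUE),
                 sd = apply(per_fold[metric_cols], 2, stats::sd, na.rm = TRUE)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", nrow(x$folds), "folds\n")
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Write a metric report as JSON (and optionally TSV)
#'
#' @param report A `metric_report` or plain named list of metrics.
#' @param path Output .json path.
#' @param tsv_path Optional per-fold TSV path.
#' @export
write_metric_report <- function(report, path, tsv_path = NULL) {
  obj <- if (inherits(report, "metric_report"))
    list(mean = as.list(report$mean), sd = as.list(report$sd),
         folds = report$folds)
  else report
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  if (!is.null(tsv_path) && inherits(report, "metric_report"))
    utils::write.table(report$folds, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
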