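# Evaluation: one-vs-rest confusion counts, accuracy / macro F1 / macro
# recall, per-class sensitivity, specificity and MCC, and the stratified
# k-fold cross-validation driver.

#' One-vs-rest confusion counts
#'
#' @param truth,predicted Integer class indices in `1..num_classes`,
#'   aligned.
#' @param num_classes Number of classes |C|.
#' @return Integer matrix `num_classes x 4` with columns TP, FP, FN, TN;
#'   each row sums to the number of samples.
#' @export
confusion_counts <- function(truth, predicted, num_classes) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted have different lengths (",
         length(truth), " vs ", length(predicted), ")")
  }
  stopifnot(all(truth >= 1 & truth <= num_classes),
            all(predicted >= 1 & predicted <= num_classes))
  n <- length(truth)
  out <- matrix(0L, num_classes, 4,
                dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (i in seq_len(num_classes)) {
    tp <- sum(truth == i & predicted == i)
    fp <- sum(truth != i & predicted == i)
    fn <- sum(truth == i & predicted != i)
    out[i, ] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  out
}

# per-class ratio with the zero-denominator policy: undefined -> 0 + flag
.safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Metrics report from confusion counts
#'
#' Multiclass accuracy is the fraction of correct predictions
#' (`sum(TP) / n`, since every correct prediction is the TP of exactly
#' one class). Per class: precision, recall (= sensitivity),
#' specificity `TN / (TN + FP)`, F1, and the one-vs-rest Matthews
#' correlation coefficient. Macro F1 and macro recall are unweighted
#' class means. Any per-class metric with a zero denominator is defined
#' as 0 and the class is flagged.
#'
#' @param counts Matrix from [confusion_counts()].
#' @param class_levels Optional class names for the per-class table.
#' @return List with `accuracy`, `macro_f1`, `macro_recall`, `per_class`
#'   (data.frame: precision, recall, sensitivity, specificity, f1, mcc),
#'   and `flagged` (classes where a denominator was zero).
#' @export
compute_metrics <- function(counts, class_levels = NULL) {
  tp <- counts[, "TP"]; fp <- counts[, "FP"]
  fn <- counts[, "FN"]; tn <- counts[, "TN"]
  n <- sum(counts[1, ])
  precision <- .safe_ratio(tp, tp + fp)
  recall <- .safe_ratio(tp, tp + fn)
  specificity <- .safe_ratio(tn, tn + fp)
  f1 <- .safe_ratio(2 * precision * recall, precision + recall)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(mcc_den == 0, 0, (tp * tn - fp * fn) / mcc_den)
  flagged <- (tp + fp) == 0 | (tp + fn) == 0 | (tn + fp) == 0 |
    (precision + recall) == 0 | mcc_den == 0
  per_class <- data.frame(precision = precision, recall = recall,
                          sensitivity = recall, specificity = specificity,
                          f1 = f1, mcc = mcc)
  if (!is.null(class_levels)) rownames(per_class) <- class_levels
  list(accuracy = sum(tp) / n,
       macro_f1 = mean(f1),
       macro_recall = mean(recall),
       per_class = per_class,
       flagged = which(flagged))
}

#' Stratified k-fold cross-validation of the meta-learned classifier
#'
#' For each fold: the held-out fold is the meta-test set; the remaining
#' samples provide the episodic meta-training tasks (a validation slice
#' is carved out of them and is available for monitoring). The meta-test
#' task fine-tunes theta' on `k_support` support samples per class from
#' the held-out fold and is scored on the remaining held-out samples.
#'
#' @param model A `meta_model` over the full pool (see
#'   [gcn_meta_model()]).
#' @param labels Pool labels.
#' @param episode An [episode_config()].
#' @param meta A [meta_config()].
#' @param folds Number of folds (default 10, minimum 2).
#' @param seed Integer seed for fold assignment and episode sampling.
#' @param real_test_only If TRUE, synthetic-provenance samples are
#'   excluded from every test query set (`provenance` required).
#' @param provenance Optional per-sample real/synthetic flags.
#' @return List with `per_fold` (data.frame of accuracy, macro_f1,
#'   macro_recall per fold), `mean` and `sd` (named numeric), `pooled`
#'   (metrics computed on the pooled predictions of all folds), and
#'   `fold_assignment`.
#' @export
cross_validate <- function(model, labels, episode, meta, folds = 10,
                           seed = 1, real_test_only = FALSE,
                           provenance = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  class_levels <- model$class_levels
  sizes <- table(factor(labels, levels = class_levels))
  if (any(sizes < folds)) {
    stop("class '", names(sizes)[which(sizes < folds)[1]],
         "' has fewer samples than folds = ", folds)
  }
  if (real_test_only && is.null(provenance)) {
    stop("real_test_only = TRUE requires provenance flags")
  }
  fa <- stratified_folds(labels, folds, seed)
  qfilter <- if (real_test_only) provenance == "real" else NULL
  per_fold <- vector("list", folds)
  pooled_truth <- integer(); pooled_pred <- integer()
  for (f in seq_len(folds)) {
    train_idx <- which(fa != f)
    test_idx <- which(fa == f)
    stream_seed <- seed + 1000L * f
    stream <- function(it) {
      tk <- sample_tasks(labels[train_idx], episode,
                         seed = stream_seed + it,
                         class_levels = class_levels)
      lapply(tk, function(t) list(
        support = model$make_data(train_idx[t$support]),
        query = model$make_data(train_idx[t$query])))
    }
    fit <- meta_train(model, stream, init = model$init(meta$seed + f),
                      meta = meta)
    task <- make_test_task(model, labels, test_idx,
                           k_support = episode$k_support,
                           seed = stream_seed, query_filter = qfilter)
    ev <- fine_tune_and_evaluate(model, task, fit$params, meta)
    per_fold[[f]] <- data.frame(fold = f, accuracy = ev$accuracy,
                                macro_f1 = ev$metrics$macro_f1,
                                macro_recall = ev$metrics$macro_recall)
    pooled_truth <- c(pooled_truth, ev$truth)
    pooled_pred <- c(pooled_pred, ev$predicted)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "macro_f1", "macro_recall")
  pooled <- compute_metrics(
    confusion_counts(pooled_truth, pooled_pred, length(class_levels)),
    class_levels)
  list(per_fold = per_fold,
       mean = vapply(per_fold[metric_cols], mean, numeric(1)),
       sd = vapply(per_fold[metric_cols], sd, numeric(1)),
       pooled = pooled,
       fold_assignment = fa)
}

#' Write a metrics report as JSON
#'
#' @param report Output of [compute_metrics()] or [cross_validate()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
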