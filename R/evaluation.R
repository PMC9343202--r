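# Evaluation: confusion counts, Acc/Sens/Spec/F-measure, PR/AP,
# ROC/AUC, stratified k-fold cross-validation, and the paired
# Student's t-test used to compare methods across folds.

#' Confusion counts at a decision threshold
#'
#' An example is predicted binding iff its score is greater than or
#' equal to `threshold` (ties predicted positive).
#'
#' @param scores binding-class probabilities in `[0, 1]`.
#' @param labels binary labels (1 = binding).
#' @param threshold decision threshold (default 0.5).
#' @return list of integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  stopifnot(all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  list(
    TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

#' Accuracy, sensitivity, specificity and F-measure
#'
#' acc = (TP + TN) / total, sens = TP / (TP + FN),
#' spec = TN / (TN + FP), F = 2 TP / (2 TP + FP + FN).
#' A division by zero (e.g. no positives at all) yields `NaN`, which
#' is reported as undefined and excluded from cross-fold means.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN`.
#' @return list `acc`, `sens`, `spec`, `f_measure`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("no evaluated pairs")
  div <- function(a, b) if (b == 0) NaN else a / b
  list(
    acc = (TP + TN) / total,
    sens = div(TP, TP + FN),
    spec = div(TN, TN + FP),
    f_measure = div(2 * TP, 2 * TP + FP + FN)
  )
}

#' Precision-recall curve and average precision
#'
#' Thresholds sweep the distinct scores in descending order; at each,
#' precision and recall are computed with the >= decision rule. AP is
#' the step-wise sum `sum_i (R_i - R_{i-1}) * P_i` (no linear
#' interpolation).
#'
#' @param scores binding-class probabilities.
#' @param labels binary labels; at least one positive required.
#' @return list with `curve` (data.frame: threshold, precision,
#'   recall) and `ap`.
#' @export
pr_curve_and_ap <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1)
  if (npos == 0) stop("average precision needs at least one positive label")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp[i] <- sum(pred & labels == 1)
    fp[i] <- sum(pred & labels == 0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / npos
  ap <- sum(diff(c(0, recall)) * precision)
  list(
    curve = data.frame(threshold = thr, precision = precision, recall = recall),
    ap = ap
  )
}

#' ROC curve and AUC
#'
#' Thresholds sweep the distinct scores descending; the area under
#' the (FPR, TPR) curve is computed by trapezoidal integration, which
#' (with simultaneous tie handling) equals the Mann-Whitney statistic
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores binding-class probabilities.
#' @param labels binary labels; both classes required.
#' @return list with `curve` (data.frame: threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_curve_and_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & labels == 1) / npos
    fpr[i] <- sum(pred & labels == 0) / nneg
  }
  xs <- c(0, fpr, 1)
  ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  list(
    curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc
  )
}

#' Full evaluation report for one set of predictions
#'
#' @param scores binding-class probabilities.
#' @param labels binary labels.
#' @param threshold decision threshold.
#' @return An `eval_report`: counts, threshold metrics, `ap`, `auc`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  counts <- confusion(scores, labels, threshold)
  m <- classification_metrics(counts)
  ap <- if (sum(labels == 1) > 0) pr_curve_and_ap(scores, labels)$ap else NaN
  auc <- if (length(unique(labels)) == 2) roc_curve_and_auc(scores, labels)$auc else NaN
  structure(
    list(counts = counts, acc = m$acc, sens = m$sens, spec = m$spec,
         f_measure = m$f_measure, ap = ap, auc = auc, threshold = threshold),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> acc %.4f | sens %.4f | spec %.4f | F %.4f | AP %.4f | AUC %.4f (thr %.2f)\n",
    x$acc, x$sens, x$spec, x$f_measure, x$ap, x$auc, x$threshold
  ))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (deterministic given `seed`) and
#' deals members round-robin over the folds, so per-fold class counts
#' deviate from perfect proportion by at most 1.
#'
#' @param ds a `site_dataset`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return The dataset with `fold_of` set (fold indices `0..k-1`,
#'   named by pair_id).
#' @export
stratified_kfold <- function(ds, k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "site_dataset"), k >= 2L)
  labels <- ds$pairs$label
  fold <- integer(nrow(ds$pairs))
  set.seed(as.integer(seed))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop(sprintf("class %d has %d members, fewer than k = %d", cls, length(idx), k))
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L) %% k
  }
  ds$fold_of <- setNames(fold, ds$pairs$pair_id)
  ds
}

#' k-fold cross-validation of the full training protocol
#'
#' Assigns stratified folds, then for each fold trains a freshly
#' initialised model on the remaining folds and evaluates on the held
#' fold. The mean report is the unweighted arithmetic mean of the fold
#' metrics (undefined metrics excluded).
#'
#' @param dataset a `site_dataset`.
#' @param constructor a [make_variant()]-style constructor, called as
#'   `constructor(dim, hidden1, hidden2, linear1, seed)`.
#' @param tables list with `mi2vec` and `m2vec` tables.
#' @param config a [train_config()].
#' @param k folds (default 5).
#' @param seed seed for the fold assignment and per-fold model seeds.
#' @param hidden1,hidden2,linear1 layer sizes passed to `constructor`.
#' @param threshold decision threshold.
#' @return list with `folds` (list of `eval_report`), `mean`
#'   (named metric means), `fold_of`.
#' @export
cross_validate <- function(dataset, constructor, tables, config = train_config(),
                           k = 5L, seed = 1L, hidden1 = 50L, hidden2 = 32L,
                           linear1 = 32L, threshold = 0.5) {
  ds <- stratified_kfold(dataset, k = k, seed = seed)
  dim <- tables$mi2vec$dim
  reports <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    test_idx <- which(ds$fold_of[ds$pairs$pair_id] == f)
    train_ds <- subset_pairs(ds, -test_idx)
    test_ds <- subset_pairs(ds, test_idx)
    model <- constructor(dim = dim, hidden1 = hidden1, hidden2 = hidden2,
                         linear1 = linear1, seed = seed + f)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_model(train_ds, model, tables, cfg)
    scores <- predict_binding(fit$model, encode_dataset(test_ds, tables$mi2vec, tables$m2vec))
    reports[[f + 1L]] <- evaluate_scores(scores, test_ds$pairs$label, threshold)
  }
  metric_names <- c("acc", "sens", "spec", "f_measure", "ap", "auc")
  means <- vapply(metric_names, function(m) {
    vals <- vapply(reports, function(r) r[[m]], numeric(1))
    mean(vals[is.finite(vals)])
  }, numeric(1))
  list(folds = reports, mean = means, fold_of = ds$fold_of)
}

#' Student's t-test between two methods' per-fold scores
#'
#' Paired by default (both methods evaluated on identical folds): the
#' t statistic is computed on the fold-wise differences with n-1
#' degrees of freedom; the p value is the two-sided tail of the t
#' distribution. When the differences have zero variance the p value
#' is reported as exactly 0 if the means differ and 1 if they are
#' equal, with a warning.
#'
#' @param fold_scores_a,fold_scores_b per-fold metric values.
#' @param paired pair by fold (default) or use Welch's two-sample test.
#' @return list with `t` and `p_value` (two-sided).
#' @export
students_t_test <- function(fold_scores_a, fold_scores_b, paired = TRUE) {
  a <- as.numeric(fold_scores_a)
  b <- as.numeric(fold_scores_b)
  if (paired) {
    if (length(a) != length(b)) stop("paired test needs equal lengths")
    if (length(a) < 2) stop("need at least two folds")
    d <- a - b
    s <- sd(d)
    if (s == 0) {
      warning("zero variance of differences; p value degenerate")
      return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                  p_value = if (mean(d) == 0) 1 else 0))
    }
    tstat <- mean(d) / (s / sqrt(length(d)))
    p <- 2 * pt(abs(tstat), df = length(d) - 1, lower.tail = FALSE)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need at least two values per group")
    va <- sd(a)^2 / length(a)
    vb <- sd(b)^2 / length(b)
    if (va + vb == 0) {
      warning("zero variance; p value degenerate")
      return(list(t = if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b)),
                  p_value = if (mean(a) == mean(b)) 1 else 0))
    }
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  list(t = tstat, p_value = p)
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `eval_report` (or the result of [cross_validate()]).
#' @param path output path.
#' @param digest optional provenance string embedded in the JSON.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, digest = NULL) {
  obj <- unclass(report)
  if (!is.null(obj$folds)) obj$folds <- lapply(obj$folds, unclass)
  if (!is.null(digest)) obj$config_digest <- digest
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export PR and ROC curve points as TSV
#'
#' @param scores,labels predictions and truth, as in [evaluate_scores()].
#' @param pr_path,roc_path output paths (either may be `NULL`).
#' @param digest optional provenance comment line.
#' @return Invisibly, a list with the two curves.
#' @export
write_curves <- function(scores, labels, pr_path = NULL, roc_path = NULL,
                         digest = NULL) {
  pr <- pr_curve_and_ap(scores, labels)
  roc <- roc_curve_and_auc(scores, labels)
  dump <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    cols <- lapply(df, function(col) sprintf("%.10g", col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  if (!is.null(pr_path)) dump(pr$curve, pr_path)
  if (!is.null(roc_path)) dump(roc$curve, roc_path)
  invisible(list(pr = pr, roc = roc))
}
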