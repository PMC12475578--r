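#' Panel-based classification and sample clustering
#'
#' The panel's srDAR methylation levels are the classification features
#' (the metric most correlated with both other panel metrics). A random
#' forest distinguishes cancer from control (binary) or all four stages
#' (multi-class); performance is reported as ROC/AUC on a stratified
#' train/test split, with multi-class AUC the unweighted macro mean of
#' one-vs-rest AUCs.
#'
#' @name classify
NULL

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random positive outscores a
#' random negative, ties half-credited; the ROC is a threshold sweep over
#' the observed scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1 or logical); both classes must occur.
#' @return list: `auc`, `roc` (data.frame fpr, tpr including the (0,0) and
#'   (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties half-credited
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

stratified_split <- function(labels, split_fraction, seed) {
  set.seed(seed)
  train <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * split_fraction))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Train and evaluate the panel classifier
#'
#' @param features region x sample methylation matrix (the panel's srDAR
#'   methylation levels); samples in columns.
#' @param stages per-sample stage labels (CTL/AIS/MIA/IAC), named or in
#'   column order.
#' @param mode `"binary"` (cancer vs CTL) or `"multiclass"` (4 stages).
#' @param split_fraction training fraction of each class (default 0.7).
#' @param seed split and forest seed.
#' @param n_trees random forest size (default 500).
#' @return list of class `classifier_report`: `mode`, `train_ids`,
#'   `test_ids`, `seed`, per-class `auc_train` / `auc_test`, macro
#'   `macro_auc_train` / `macro_auc_test`, and `roc_test` (per class).
#' @export
train_eval_classifier <- function(features, stages,
                                  mode = c("binary", "multiclass"),
                                  split_fraction = 0.7, seed = 1L,
                                  n_trees = 500) {
  mode <- match.arg(mode)
  stages <- as.character(stages)
  stopifnot(ncol(features) == length(stages))
  x <- t(features)
  x[!is.finite(x)] <- 0.5  # absent metric -> uninformative midpoint
  y <- if (mode == "binary")
    factor(ifelse(stages == "CTL", "CTL", "cancer"),
           levels = c("CTL", "cancer"))
  else factor(stages, levels = STAGES)
  if (any(table(y) < 4)) stop("need >= 4 samples per class")

  train <- stratified_split(y, split_fraction, seed)
  test <- setdiff(seq_along(y), train)
  if (length(unique(y[train])) < nlevels(y) ||
      length(unique(y[test])) < nlevels(y))
    stop("a class is absent from the train or test split")
  set.seed(seed)
  rf <- randomForest::randomForest(x[train, , drop = FALSE], y[train],
                                   ntree = n_trees)
  eval_split <- function(idx) {
    prob <- stats::predict(rf, x[idx, , drop = FALSE], type = "prob")
    aucs <- vapply(levels(y), function(cl)
      roc_auc(prob[, cl], y[idx] == cl)$auc, numeric(1))
    aucs
  }
  auc_train <- eval_split(train)
  auc_test <- eval_split(test)
  prob_test <- stats::predict(rf, x[test, , drop = FALSE], type = "prob")
  roc_test <- lapply(stats::setNames(levels(y), levels(y)), function(cl)
    roc_auc(prob_test[, cl], y[test] == cl)$roc)
  structure(list(mode = mode,
                 train_ids = colnames(features)[train],
                 test_ids = colnames(features)[test], seed = seed,
                 auc_train = auc_train, auc_test = auc_test,
                 macro_auc_train = mean(auc_train),
                 macro_auc_test = mean(auc_test),
                 roc_test = roc_test),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s classifier (seed %d): train macro AUC %.3f, test macro AUC %.3f\n",
              x$mode, x$seed, x$macro_auc_train, x$macro_auc_test))
  invisible(x)
}

#' Hierarchical clustering of samples on panel methylation
#'
#' Ward linkage on Euclidean distance over region-methylation vectors.
#' Samples whose metrics are entirely absent are excluded with a warning.
#'
#' @param features region x sample methylation matrix.
#' @param k optional number of flat clusters.
#' @return list: `hclust` (dendrogram), `labels` (named cluster labels when
#'   k given, else NULL), `excluded` (dropped sample ids).
#' @export
hierarchical_cluster_samples <- function(features, k = NULL) {
  all_na <- apply(features, 2, function(v) all(!is.finite(v)))
  excluded <- colnames(features)[all_na]
  if (length(excluded) > 0)
    warning("excluding samples with no defined metrics: ",
            paste(excluded, collapse = ", "))
  f <- features[, !all_na, drop = FALSE]
  if (ncol(f) < 2) stop("need >= 2 samples with defined metrics")
  f <- f[, order(colnames(f)), drop = FALSE]  # order-invariant partition
  x <- t(f)
  x[!is.finite(x)] <- 0.5
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels, excluded = excluded)
}
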