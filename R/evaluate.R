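#' Confusion counts
#'
#' @param true,pred equal-length 0/1 vectors (1 = case).
#' @return list of class `ConfusionCounts` with `TP`, `TN`, `FP`, `FN`, `N`.
#' @export
confusion <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (length(true) == 0L) stop("empty input")
  true <- as.integer(true); pred <- as.integer(pred)
  structure(list(TP = sum(true == 1L & pred == 1L),
                 TN = sum(true == 0L & pred == 0L),
                 FP = sum(true == 0L & pred == 1L),
                 FN = sum(true == 1L & pred == 0L),
                 N = length(true)),
            class = "ConfusionCounts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP+TN)/N`, `Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`. A metric
#' whose denominator is zero is returned as `NA` with a warning.
#'
#' @param counts a `ConfusionCounts`.
#' @return named list `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  if (counts$N == 0L) stop("empty confusion table")
  sens <- if (counts$TP + counts$FN == 0L) {
    warning("no positive truths: sensitivity undefined"); NA_real_
  } else counts$TP / (counts$TP + counts$FN)
  spec <- if (counts$TN + counts$FP == 0L) {
    warning("no negative truths: specificity undefined"); NA_real_
  } else counts$TN / (counts$TN + counts$FP)
  list(accuracy = (counts$TP + counts$TN) / counts$N,
       sensitivity = sens, specificity = spec)
}

# trapezoidal AUC over the empirical ROC; ties contribute half
.auc_trapezoid <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (tpr[ord][-1L] + tpr[ord][-length(tpr)]) / 2)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Builds the ROC over all distinct score cutoffs under the rule
#' `score >= cutoff -> case`, with sentinel endpoints (sensitivity 1 /
#' specificity 0 and 0 / 1). The AUC is the trapezoidal area, so tied
#' case/control scores contribute half per tied pair (equal to the
#' Mann-Whitney concordance statistic).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels, both classes present.
#' @return list of class `ROCCurve` with `cutoffs`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  .assert_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  cuts <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(cuts, function(th) sum(scores >= th & labels == 1L) / n1,
                 numeric(1L))
  spec <- vapply(cuts, function(th) sum(scores < th & labels == 0L) / n0,
                 numeric(1L))
  auc <- .auc_trapezoid(c(1 - spec, 1), c(sens, 1))
  structure(list(cutoffs = cuts, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat("ROCCurve:", length(x$cutoffs), "cutoffs, AUC =",
      signif(x$auc, 4L), "\n")
  invisible(x)
}

# stratified indices for the training half; resamples (with a message) if a
# class would be empty on either side
.stratified_train_idx <- function(y, train_fraction) {
  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  k1 <- round(train_fraction * length(idx1))
  k0 <- round(train_fraction * length(idx0))
  k1 <- min(max(k1, 2L), length(idx1) - 1L)
  k0 <- min(max(k0, 2L), length(idx0) - 1L)
  if (k1 < 2L || k0 < 2L) {
    stop("too few samples per class for a stratified split")
  }
  sort(c(sample(idx1, k1), sample(idx0, k0)))
}

# one split-fit-evaluate cycle on plain matrices; returns accuracy and AUC
# on the held-out samples
.split_fit_eval <- function(X, y, train_idx, n_components = 1L) {
  fw <- .pls_weights(X[train_idx, , drop = FALSE], y[train_idx], n_components)
  std_scores <- function(idx) {
    Xs <- sweep(sweep(X[idx, names(fw$weights), drop = FALSE], 2L,
                      fw$center), 2L, fw$scale, "/")
    as.numeric(Xs %*% fw$weights)
  }
  theta <- select_threshold(std_scores(train_idx), y[train_idx])
  test_idx <- setdiff(seq_along(y), train_idx)
  sc <- std_scores(test_idx)
  yt <- y[test_idx]
  pred <- as.integer(sc >= theta)
  list(accuracy = mean(pred == yt), auc = roc_auc(sc, yt)$auc,
       correct = sum(pred == yt), incorrect = sum(pred != yt))
}

#' Repeated random-split validation
#'
#' Repeatedly splits the samples into stratified random training and test
#' halves, fits the PLS classifier (weights and threshold from the training
#' half only), and records test accuracy and AUC; summaries are the mean and
#' standard deviation over repeats.
#'
#' @param ds a complete `ExpressionDataset`.
#' @param genes predictor `GeneSet` or character vector.
#' @param n_repeats number of random splits (default 100).
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.5).
#' @param n_components PLS components (default 1).
#' @param seed RNG seed for the split stream.
#' @return an `EvaluationSummary`: per-repeat `accuracy` (percent) and `auc`,
#'   their means and SDs, and the split specification.
#' @export
repeated_split_eval <- function(ds, genes, n_repeats = 100,
                                train_fraction = 0.5, n_components = 1L,
                                seed = 1) {
  .assert_binary_labels(ds$labels)
  xy <- .xy_from_dataset(ds, genes)
  acc <- auc <- numeric(n_repeats)
  withr::with_seed(.sub_seed(seed, "split"), {
    for (r in seq_len(n_repeats)) {
      idx <- .stratified_train_idx(xy$y, train_fraction)
      res <- .split_fit_eval(xy$X, xy$y, idx, n_components)
      acc[r] <- 100 * res$accuracy
      auc[r] <- res$auc
    }
  })
  structure(list(accuracy = acc, auc = auc,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 auc_mean = mean(auc), auc_sd = stats::sd(auc),
                 n_repeats = n_repeats, train_fraction = train_fraction,
                 seed = seed),
            class = "EvaluationSummary")
}

#' @export
print.EvaluationSummary <- function(x, ...) {
  cat(sprintf("EvaluationSummary over %d repeats:\n", x$n_repeats))
  cat(sprintf("  accuracy %.2f%% +/- %.2f\n", x$accuracy_mean,
              if (x$n_repeats > 1L) x$accuracy_sd else 0))
  cat(sprintf("  AUC      %.3f +/- %.3f\n", x$auc_mean,
              if (x$n_repeats > 1L) x$auc_sd else 0))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the samples into k stratified folds (sizes differing by at
#' most one within each class), trains on k-1 folds and evaluates the
#' held-out fold, returning one ROC curve per fold.
#'
#' @param ds a complete `ExpressionDataset`.
#' @param genes predictor `GeneSet` or character vector.
#' @param k number of folds (default 5); must not exceed the minority class
#'   size.
#' @param n_components PLS components (default 1).
#' @param seed RNG seed for fold assignment.
#' @return list of `ROCCurve`s (one per fold) with an attribute `folds`
#'   giving the test-sample indices of each fold.
#' @export
kfold_cv <- function(ds, genes, k = 5, n_components = 1L, seed = 1) {
  .assert_binary_labels(ds$labels)
  k <- as.integer(k)
  n1 <- sum(ds$labels == 1L); n0 <- sum(ds$labels == 0L)
  if (k < 2L) stop("k must be at least 2")
  if (k > min(n1, n0)) stop("k exceeds the minority class size")
  xy <- .xy_from_dataset(ds, genes)
  folds <- withr::with_seed(.sub_seed(seed, "split"), {
    f <- integer(length(xy$y))
    for (cls in c(0L, 1L)) {
      idx <- which(xy$y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  curves <- lapply(seq_len(k), function(fold) {
    train_idx <- which(folds != fold)
    fw <- .pls_weights(xy$X[train_idx, , drop = FALSE], xy$y[train_idx],
                       n_components)
    test_idx <- which(folds == fold)
    Xs <- sweep(sweep(xy$X[test_idx, names(fw$weights), drop = FALSE], 2L,
                      fw$center), 2L, fw$scale, "/")
    roc_auc(as.numeric(Xs %*% fw$weights), xy$y[test_idx])
  })
  attr(curves, "folds") <- split(seq_along(folds), folds)
  curves
}
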