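# Performance metrics and the n-fold cross-validation protocol.

#' Confusion counts for +1/-1 classification
#'
#' @param y_true true labels in +1/-1.
#' @param y_pred predicted labels in +1/-1.
#' @return a `confusion_counts` list with `tp`, `fn`, `tn`, `fp`. tp + fn is
#'   the total number of positives and tn + fp the total negatives.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(-1L, 1L))) {
    stop("labels must be +1 or -1")
  }
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == -1L),
                 tn = sum(y_true == -1L & y_pred == -1L),
                 fp = sum(y_true == -1L & y_pred == 1L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and Matthews correlation coefficient
#'
#' Sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
#' accuracy = (tp + tn) / N, and
#' MCC = (tn * tp - fp * fn) / sqrt((tp+fn)(tp+fp)(tn+fn)(tn+fp)).
#' A class absent from the truth makes the corresponding rate NA; a zero MCC
#' denominator yields MCC = 0 (the usual convention for degenerate tables).
#'
#' @param cc a `confusion_counts`.
#' @return named numeric vector `(sensitivity, specificity, accuracy, mcc)`.
#' @export
classification_metrics <- function(cc) {
  tp <- as.numeric(cc$tp); fn <- as.numeric(cc$fn)
  tn <- as.numeric(cc$tn); fp <- as.numeric(cc$fp)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  mcc <- if (denom > 0) (tn * tp - fp * fn) / denom else 0
  c(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

#' ROC curve and area under it
#'
#' Threshold-free AUC over the real-valued decision scores, computed as the
#' normalised Mann-Whitney rank statistic (ties contribute 1/2, i.e. tied
#' ranks are averaged); the returned curve is the standard staircase of
#' (false positive rate, true positive rate) points.
#'
#' @param y_true labels in +1/-1, both classes present.
#' @param scores real decision values, larger meaning more positive.
#' @return list with `curve` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (!all(y_true %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == -1L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)                          # average ranks on ties
  auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == -1L) / n0,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

# Stratified fold assignment: members of each class are shuffled and dealt
# round-robin, with the dealing position carried over between classes so
# overall fold sizes differ by at most one.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  shift <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    if (length(idx) < n_folds) {
      stop("class ", cls, " has fewer samples (", length(idx),
           ") than folds (", n_folds, ")")
    }
    fold[idx] <- ((seq_along(idx) - 1L + shift) %% n_folds) + 1L
    shift <- (shift + length(idx)) %% n_folds
  }
  fold
}

#' n-fold cross-validation of the succinylation classifier
#'
#' The protocol: randomly partition the dataset into n stratified parts of
#' roughly equal size, hold one part out, train on the remaining n - 1, score
#' the held-out part with all metrics, rotate over the n parts and average.
#' By default the input dataset is used as given (so if it was balanced
#' beforehand, eliminated negatives never reappear -- the evaluation design
#' this package reproduces); `balance_within_folds = TRUE` instead runs the
#' k-nearest-neighbour elimination on each training portion only, leaving
#' validation folds untouched, for a leakage-free variant.
#'
#' @param data a `succ_dataset` with both classes.
#' @param n_folds number of folds (6, 8 and 10 are the conventional choices).
#' @param params named list of [svm_train()] arguments (C, gamma, ...).
#' @param seed integer seed controlling the partition.
#' @param balance_within_folds apply balancing to training folds only.
#' @param balance_params named list of [balance_dataset()] arguments.
#' @return a `cv_report`: `n_folds`, `per_fold` (data frame of sensitivity,
#'   specificity, accuracy, mcc, auc per fold), `means`, and `seed`.
#' @export
cross_validate <- function(data, n_folds = 10, params = list(), seed = 1,
                           balance_within_folds = FALSE,
                           balance_params = list()) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  fold <- with_seed(seed, stratified_folds(data$y, n_folds))
  per_fold <- matrix(NA_real_, nrow = n_folds, ncol = 5,
                     dimnames = list(NULL, c("sensitivity", "specificity",
                                             "accuracy", "mcc", "auc")))
  for (f in seq_len(n_folds)) {
    train <- dataset_subset(data, fold != f)
    test <- dataset_subset(data, fold == f)
    if (balance_within_folds) {
      train <- do.call(balance_dataset, c(list(train), balance_params))$data
    }
    model <- do.call(svm_train, c(list(train), params))
    scores <- svm_decision(model, test$X)
    pred <- ifelse(scores >= 0, 1L, -1L)
    m <- classification_metrics(confusion_counts(test$y, pred))
    per_fold[f, ] <- c(m, auc = roc_auc(test$y, scores)$auc)
  }
  per_fold <- as.data.frame(per_fold)
  structure(list(n_folds = n_folds, per_fold = per_fold,
                 means = colMeans(per_fold), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$n_folds, x$seed))
  print(round(rbind(x$per_fold, mean = x$means), 4))
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
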