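#' Stratified independent split plus cross-validation fold plan
#'
#' Holds out a stratified fraction (default 1/5) as the independent test
#' set and assigns the remaining rows to stratified cross-validation folds
#' (default 10).
#'
#' @param labels class factor over all rows.
#' @param seed RNG seed.
#' @param test_frac held-out fraction; default 0.2.
#' @param folds number of CV folds; default 10.
#' @return a `split_plan`: list with `test_idx`, `fold` (integer per row,
#'   `NA` on test rows), `seed`.
#' @export
make_split <- function(labels, seed, test_frac = 0.2, folds = 10) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < folds))
    stop("class too small for stratification (need >= ", folds,
         " training candidates per class)")
  set.seed(seed)
  n <- length(labels)
  fold <- rep(NA_integer_, n)
  test <- logical(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    n_test <- max(1L, round(length(idx) * test_frac))
    test[idx[seq_len(n_test)]] <- TRUE
    train_idx <- idx[-seq_len(n_test)]
    fold[train_idx] <- rep(seq_len(folds), length.out = length(train_idx))
  }
  structure(list(test_idx = which(test), fold = fold, seed = seed,
                 folds = folds),
            class = "split_plan")
}

#' Confusion matrix from true and predicted class factors
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,predicted factors with identical level sets.
#' @return a K x K integer matrix.
#' @export
confusion_matrix <- function(truth, predicted) {
  predicted <- factor(predicted, levels = levels(truth))
  unclass(table(truth = truth, predicted = predicted))
}

check_cm <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  invisible(TRUE)
}

#' Overall accuracy and error rate of a confusion matrix
#'
#' `error_rate(cm)` is exactly `1 - accuracy(cm)`.
#'
#' @param cm confusion matrix (true x predicted counts).
#' @return a scalar.
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' @rdname accuracy
#' @export
error_rate <- function(cm) 1 - accuracy(cm)

## Rank-based (Mann-Whitney) AUC with midrank tie handling.
auc_midrank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_mcc <- function(tp, fp, tn, fn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warning("degenerate 2x2 margin; MCC set to 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

#' One-vs-rest per-class metrics
#'
#' Collapses the confusion matrix to a 2x2 table per class and reports
#' binary accuracy, specificity, sensitivity and MCC, plus the rank-based
#' AUC of the class's probability score (midrank ties).
#'
#' @param cm K x K confusion matrix (true x predicted).
#' @param scores optional samples x K matrix of per-class probability
#'   scores (columns in class order); omit to skip AUC.
#' @param truth class factor for `scores`' rows.
#' @return a data frame with one row per class: `class`, `acc`, `sp`, `sn`,
#'   `mcc`, `auc`.
#' @export
per_class_metrics <- function(cm, scores = NULL, truth = NULL) {
  check_cm(cm)
  K <- nrow(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(K))
  total <- sum(cm)
  out <- data.frame(class = classes, acc = NA_real_, sp = NA_real_,
                    sn = NA_real_, mcc = NA_real_, auc = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(K)) {
    tp <- cm[j, j]
    fn <- sum(cm[j, ]) - tp
    fp <- sum(cm[, j]) - tp
    tn <- total - tp - fn - fp
    out$sn[j] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$sp[j] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    out$acc[j] <- (tp + tn) / total
    out$mcc[j] <- binary_mcc(tp, fp, tn, fn)
    if (!is.null(scores)) {
      out$auc[j] <- auc_midrank(scores[, j], truth == classes[j])
    }
  }
  out
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-category correlation generalization computed from the full
#' confusion matrix: `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) *
#' (s^2 - sum(t_k^2)))` with `c` the trace, `s` the total, and `t`, `p`
#' the true/predicted margins. Reduces to the binary MCC for K = 2.
#'
#' @param cm K x K confusion matrix.
#' @return a scalar in \[-1, 1\].
#' @export
multiclass_mcc <- function(cm) {
  check_cm(cm)
  s <- sum(cm); c0 <- sum(diag(cm))
  t <- rowSums(cm); p <- colSums(cm)
  denom <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (denom == 0) {
    warning("zero-variance margin; multiclass MCC set to 0")
    return(0)
  }
  (c0 * s - sum(p * t)) / denom
}

#' Confusion entropy (CEN)
#'
#' An entropy over the off-diagonal confusion probabilities. For class j,
#' the misclassification probabilities are
#' `P^j_(i,j) = C[i,j] / sum_k(C[j,k] + C[k,j])` and
#' `P^j_(j,i) = C[j,i] / (same denominator)`; the class entropy uses
#' logarithms base `2(K-1)` over the off-diagonal terms and classes are
#' weighted by `w_j = sum_k(C[j,k] + C[k,j]) / (2 * total)`. A perfect
#' diagonal gives 0; heavier confusion gives larger values.
#'
#' @param cm K x K confusion matrix, K >= 2.
#' @return a non-negative scalar.
#' @export
cen <- function(cm) {
  check_cm(cm)
  K <- nrow(cm)
  if (K < 2) stop("CEN needs at least two classes")
  total <- sum(cm)
  base <- 2 * (K - 1)
  val <- 0
  for (j in seq_len(K)) {
    denom_j <- sum(cm[j, ]) + sum(cm[, j])
    if (denom_j == 0) next
    w_j <- denom_j / (2 * total)
    h <- 0
    for (i in seq_len(K)) {
      if (i == j) next
      pji <- cm[j, i] / denom_j
      pij <- cm[i, j] / denom_j
      if (pji > 0) h <- h - pji * log(pji, base)
      if (pij > 0) h <- h - pij * log(pij, base)
    }
    val <- val + w_j * h
  }
  val
}

#' DeLong test for two correlated ROC AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors over the same
#' samples (paired), via the fast DeLong variance estimate and a two-sided
#' normal p-value. Delegates to [pROC::roc.test()].
#'
#' @param scores_a,scores_b numeric score vectors over the same samples.
#' @param binary_truth logical (or 0/1) vector; must contain both classes.
#' @return a list with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, binary_truth) {
  binary_truth <- as.logical(binary_truth)
  if (length(unique(binary_truth)) < 2)
    stop("binary_truth must contain both classes")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(binary_truth))
    stop("score and truth vectors must have equal length")
  auc_a <- auc_midrank(scores_a, binary_truth)
  auc_b <- auc_midrank(scores_b, binary_truth)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = auc_a, auc_b = auc_b, p_value = 1))
  }
  ra <- pROC::roc(binary_truth, scores_a, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  rb <- pROC::roc(binary_truth, scores_b, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = auc_a, auc_b = auc_b, p_value = as.numeric(tst$p.value))
}

#' Fit a random forest on a labelled feature matrix
#'
#' Defaults: 500 trees, `sqrt(p)` candidate features per split, unlimited
#' depth, impurity importance, single-threaded for reproducibility.
#'
#' @param X samples x features matrix.
#' @param labels class factor.
#' @param num_trees,mtry,seed forest hyperparameters.
#' @return a `ranger` probability forest.
#' @export
train_rf <- function(X, labels, num_trees = 500, mtry = NULL, seed = 1L) {
  df <- as.data.frame(X)
  df$.class <- factor(labels)
  ranger::ranger(dependent.variable.name = ".class", data = df,
                 num.trees = num_trees,
                 mtry = if (is.null(mtry)) floor(sqrt(ncol(X))) else mtry,
                 probability = TRUE, importance = "impurity",
                 seed = seed, num.threads = 1)
}

## Per-class probability predictions from a ranger probability forest.
predict_rf <- function(rf, X, classes) {
  pr <- stats::predict(rf, data = as.data.frame(X), num.threads = 1)$predictions
  pr[, classes, drop = FALSE]
}

#' Aggregate feature importances by encoding scheme
#'
#' Sums impurity importances per scheme (normalised to total 1) and ranks
#' individual features with their human-readable tags. Schemes present in
#' `all_schemes` but absent from the fitted columns report 0.
#'
#' @param model a fitted `ranger` forest, or a named numeric importance
#'   vector.
#' @param provenance data frame with columns `scheme`, `tag`, one row per
#'   fitted column (post-filter order).
#' @param all_schemes optional scheme universe; defaults to those present.
#' @return a list with `by_scheme` (named, sums to 1) and `features`
#'   (ranked data frame: scheme, tag, importance).
#' @export
aggregate_importance <- function(model, provenance, all_schemes = NULL) {
  imp <- if (inherits(model, "ranger")) ranger::importance(model) else model
  if (length(imp) != nrow(provenance))
    stop("provenance does not match the number of fitted features")
  imp <- pmax(as.numeric(imp), 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  if (is.null(all_schemes)) all_schemes <- unique(provenance$scheme)
  by_scheme <- vapply(all_schemes, function(s)
    sum(imp[provenance$scheme == s]), numeric(1))
  ord <- order(imp, decreasing = TRUE)
  list(by_scheme = sort(by_scheme, decreasing = TRUE),
       features = data.frame(scheme = provenance$scheme[ord],
                             tag = provenance$tag[ord],
                             importance = imp[ord],
                             stringsAsFactors = FALSE))
}

#' Summary metrics for one evaluation
#'
#' @param cm confusion matrix.
#' @param scores optional per-class probability matrix.
#' @param truth class factor for `scores`' rows.
#' @return a `metrics_report`: list with `acc`, `error`, `mcc`, `cen`,
#'   `per_class` and the confusion matrix.
#' @export
metrics_report <- function(cm, scores = NULL, truth = NULL) {
  structure(list(acc = accuracy(cm), error = error_rate(cm),
                 mcc = multiclass_mcc(cm), cen = cen(cm),
                 per_class = per_class_metrics(cm, scores, truth),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Acc %.4f  MCC %.4f  CEN %.4f  E %.4f\n",
              x$acc, x$mcc, x$cen, x$error))
  print(x$per_class, digits = digits)
  invisible(x)
}
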