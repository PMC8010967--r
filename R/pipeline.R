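#' Options for the end-to-end classification pipeline
#'
#' @param schemes encoder schemes to use (see [encode_all()]).
#' @param filter_mode,filter_threshold Pearson screen settings
#'   (see [fit_pcc_filter()]).
#' @param augment `"none"`, `"cgan"`, `"cwgan"` or `"smote"`.
#' @param augment_scope `"fold"` (default: augmentation refit inside each
#'   training fold) or `"once"` (single augmentation of the full training
#'   split before fold assignment — leaks synthetic information across
#'   folds; provided for comparison only).
#' @param gan gan training configuration ([gan_config()]).
#' @param num_trees,mtry random-forest hyperparameters.
#' @param seed seed for forest fitting.
#' @return a `pipeline_options` list.
#' @export
pipeline_options <- function(schemes = c("AAindex", "CKSAAP", "PWM",
                                         "ReducedAlphabet", "FoldAmyloid",
                                         "BE", "PC-PseAAC", "SC-PseAAC",
                                         "Structure"),
                             filter_mode = "feature-label",
                             filter_threshold = 0.5,
                             augment = "none",
                             augment_scope = c("fold", "once"),
                             gan = gan_config(iterations = 300),
                             num_trees = 500, mtry = NULL, seed = 1L) {
  structure(list(schemes = schemes, filter_mode = filter_mode,
                 filter_threshold = filter_threshold, augment = augment,
                 augment_scope = match.arg(augment_scope), gan = gan,
                 num_trees = num_trees, mtry = mtry, seed = seed),
            class = "pipeline_options")
}

#' Run one train/evaluate fold of the full pipeline
#'
#' Everything that is fitted — the position weight matrix, the Pearson
#' selection mask, the GAN and its feature scaler, and the random forest —
#' is fitted on the training rows only; augmentation is applied to the
#' training rows only, so evaluation rows are never synthetic.
#'
#' @param data list with `dataset` (a `lys_dataset`) and optional
#'   `structure` table.
#' @param train_idx,eval_idx disjoint row indices into the dataset.
#' @param options a [pipeline_options()].
#' @return a `fold_result`: confusion matrix, per-class `scores`, `truth`,
#'   `predicted`, fitted `pwm`, `mask`, `rf`, `importance`, `augmentation`.
#' @export
run_pipeline_fold <- function(data, train_idx, eval_idx, options = pipeline_options()) {
  stopifnot(length(intersect(train_idx, eval_idx)) == 0)
  fr <- data$dataset$fragments
  classes <- data$dataset$classes
  tr <- fr[train_idx, , drop = FALSE]
  ev <- fr[eval_idx, , drop = FALSE]
  pwm <- fit_pwm(tr$sequence)
  enc_tr <- encode_dataset(tr, pwm = pwm, structure = data$structure,
                           schemes = options$schemes)
  enc_ev <- encode_dataset(ev, pwm = pwm, structure = data$structure,
                           schemes = options$schemes)
  mask <- fit_pcc_filter(enc_tr$X, tr$class, mode = options$filter_mode,
                         threshold = options$filter_threshold,
                         provenance = enc_tr$provenance)
  Xtr <- apply_pcc_filter(mask, enc_tr$X)
  Xev <- apply_pcc_filter(mask, enc_ev$X)
  aug <- augment_dataset(Xtr, tr$class, method = options$augment,
                         config = options$gan)
  rf <- train_rf(aug$X, aug$labels, num_trees = options$num_trees,
                 mtry = options$mtry, seed = options$seed)
  scores <- predict_rf(rf, Xev, classes)
  predicted <- factor(classes[max.col(scores, ties.method = "first")],
                      levels = classes)
  truth <- factor(ev$class, levels = classes)
  cm <- confusion_matrix(truth, predicted)
  structure(list(confusion = cm, scores = scores, truth = truth,
                 predicted = predicted, pwm = pwm, mask = mask, rf = rf,
                 importance = aggregate_importance(rf, mask$provenance,
                                                   all_schemes = unique(enc_tr$provenance$scheme)),
                 augmentation = aug[c("deficits", "synthetic")],
                 eval_idx = eval_idx),
            class = "fold_result")
}

#' Full evaluation protocol: stratified CV plus independent test
#'
#' Splits the data 4/5 train : 1/5 independent test (stratified), runs
#' stratified cross-validation on the training part (fold predictions
#' pooled into one confusion matrix), then fits on the whole training part
#' and scores the independent test set.
#'
#' @param data list with `dataset` (`lys_dataset`) and optional `structure`.
#' @param options a [pipeline_options()].
#' @param seed split seed.
#' @param folds number of CV folds; default 10.
#' @param run_cv set `FALSE` to skip cross-validation and only run the
#'   independent test.
#' @return a list with `cv` and `independent` (`metrics_report`s),
#'   `importance` (from the independent-test model), `split`.
#' @export
evaluate_pipeline <- function(data, options = pipeline_options(), seed = 1L,
                              folds = 10, run_cv = TRUE) {
  labels <- data$dataset$fragments$class
  split <- make_split(labels, seed = seed, folds = folds)
  train_all <- which(!is.na(split$fold))
  cv_report <- NULL
  if (run_cv) {
    truths <- list(); preds <- list(); scores <- list()
    for (f in seq_len(folds)) {
      ev <- which(split$fold == f)
      tr <- setdiff(train_all, ev)
      res <- run_pipeline_fold(data, tr, ev, options)
      truths[[f]] <- res$truth; preds[[f]] <- res$predicted
      scores[[f]] <- res$scores
    }
    truth_cv <- factor(unlist(lapply(truths, as.character)),
                       levels = data$dataset$classes)
    pred_cv <- factor(unlist(lapply(preds, as.character)),
                      levels = data$dataset$classes)
    score_cv <- do.call(rbind, scores)
    cv_report <- metrics_report(confusion_matrix(truth_cv, pred_cv),
                                score_cv, truth_cv)
  }
  ind <- run_pipeline_fold(data, train_all, split$test_idx, options)
  ind_report <- metrics_report(ind$confusion, ind$scores, ind$truth)
  list(cv = cv_report, independent = ind_report,
       importance = ind$importance, split = split)
}

#' Write a metrics report as JSON (plus confusion-matrix CSV)
#'
#' @param report a `metrics_report`.
#' @param path output JSON path; the confusion matrix goes to the same
#'   path with extension `.confusion.csv`.
#' @export
write_metrics_report <- function(report, path) {
  obj <- list(acc = report$acc, error = report$error, mcc = report$mcc,
              cen = report$cen, per_class = report$per_class)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(as.data.frame(report$confusion),
                   sub("\\.json$", ".confusion.csv", path),
                   row.names = FALSE)
  invisible(path)
}
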