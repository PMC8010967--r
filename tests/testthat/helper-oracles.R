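# Independent oracle: multiclass MCC as the Pearson correlation between the
# one-hot expansions of truth and prediction, computed sample-by-sample.
mcc_onehot_oracle <- function(cm) {
  K <- nrow(cm)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    truth <- c(truth, rep(i, cm[i, j])); pred <- c(pred, rep(j, cm[i, j]))
  }
  X <- outer(truth, seq_len(K), "=="); Y <- outer(pred, seq_len(K), "==")
  num <- sum(vapply(seq_len(K), function(k)
    sum((X[, k] - mean(X[, k])) * (Y[, k] - mean(Y[, k]))), numeric(1)))
  dx <- sum(vapply(seq_len(K), function(k)
    sum((X[, k] - mean(X[, k]))^2), numeric(1)))
  dy <- sum(vapply(seq_len(K), function(k)
    sum((Y[, k] - mean(Y[, k]))^2), numeric(1)))
  num / sqrt(dx * dy)
}
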