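test_that("accuracy and error rate are complementary", {
  cm <- diag(c(10, 20, 30))
  expect_equal(accuracy(cm), 1)
  expect_equal(error_rate(cm), 0)
  cm2 <- matrix(c(8549, 0, 1451, 0), 2)
  expect_equal(accuracy(cm2), 0.8549)
  expect_equal(error_rate(cm2), 0.1451)
  set.seed(30)
  cm3 <- matrix(rpois(49, 5), 7)
  expect_equal(error_rate(cm3), 1 - accuracy(cm3))
  expect_error(accuracy(matrix(0, 3, 3)), "empty")
})

test_that("one-vs-rest collapse matches exhaustive counts on a 30-sample toy", {
  set.seed(31)
  truth <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
  pred <- factor(sample(c("a", "b", "c"), 30, replace = TRUE),
                 levels = levels(truth))
  cm <- confusion_matrix(truth, pred)
  m <- per_class_metrics(cm)
  for (cl in levels(truth)) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    row <- m[m$class == cl, ]
    expect_equal(row$sn, tp / (tp + fn))
    expect_equal(row$sp, tn / (tn + fp))
    expect_equal(row$acc, (tp + tn) / 30)
    expect_equal(row$mcc,
                 (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  }
  # perfect classifier saturates every per-class metric
  scores <- outer(as.integer(truth), 1:3, function(i, k) as.numeric(i == k))
  mp <- per_class_metrics(confusion_matrix(truth, truth), scores, truth)
  expect_equal(mp$sn, rep(1, 3))
  expect_equal(mp$sp, rep(1, 3))
  expect_equal(mp$mcc, rep(1, 3))
  expect_equal(mp$auc, rep(1, 3))
  # a class never predicted has zero sensitivity
  pred_ab <- factor(ifelse(truth == "c", "a", as.character(truth)),
                    levels = levels(truth))
  expect_warning(m2 <- per_class_metrics(confusion_matrix(truth, pred_ab)),
                 "degenerate")
  expect_equal(m2$sn[m2$class == "c"], 0)
})

test_that("multiclass MCC matches the one-hot correlation oracle", {
  expect_equal(multiclass_mcc(diag(c(5, 7, 9))), 1)
  expect_equal(multiclass_mcc(matrix(3, 4, 4)), 0)
  set.seed(32)
  for (rep in 1:8) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 4), K) + diag(K)  # ensure nonzero margins
    expect_equal(multiclass_mcc(cm), mcc_onehot_oracle(cm), tolerance = 1e-12)
  }
  # K = 2 reduces to the binary MCC formula
  for (rep in 1:5) {
    cm <- matrix(rpois(4, 6) + 1, 2)
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    expect_equal(multiclass_mcc(cm),
                 (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  }
})

test_that("confusion entropy matches a term-by-term evaluation and is symmetric", {
  expect_equal(cen(diag(c(4, 5, 6))), 0)
  cm <- matrix(c(20, 3, 1,
                 2, 15, 4,
                 0, 5, 10), 3, byrow = TRUE)
  # independent summation: enumerate all off-diagonal probability terms
  total <- sum(cm); K <- 3; base <- 2 * (K - 1)
  expected <- 0
  for (j in 1:K) {
    denom <- sum(cm[j, ]) + sum(cm[, j])
    terms <- c(cm[j, -j], cm[-j, j]) / denom
    terms <- terms[terms > 0]
    expected <- expected + (denom / (2 * total)) *
      sum(-terms * log(terms) / log(base))
  }
  expect_equal(cen(cm), expected, tolerance = 1e-12)
  # permuting class order leaves CEN unchanged
  perm <- c(3, 1, 2)
  expect_equal(cen(cm[perm, perm]), cen(cm), tolerance = 1e-12)
  expect_error(cen(matrix(5, 1, 1)), "two classes")
})

test_that("DeLong test agrees with rank AUCs and a permutation oracle", {
  set.seed(33)
  truth <- rep(c(TRUE, FALSE), each = 20)
  a <- rnorm(40, mean = ifelse(truth, 1, 0))
  b <- a * 0.5 + rnorm(40, sd = 0.8)
  res <- delong_test(a, b, truth)
  # AUCs are the package's own rank-based values
  m <- per_class_metrics(confusion_matrix(factor(truth), factor(truth)),
                         cbind(1 - a, a), factor(truth))
  expect_equal(res$auc_a, m$auc[2])
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # identical scores: zero AUC difference, p = 1
  same <- delong_test(a, a, truth)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
  # paired permutation oracle: swap the two scores within random samples
  auc_diff <- function(x, y) abs(lysgan:::auc_midrank(x, truth) -
                                   lysgan:::auc_midrank(y, truth))
  obs <- auc_diff(a, b)
  nperm <- 1000
  perm <- replicate(nperm, {
    swap <- runif(40) < 0.5
    a2 <- ifelse(swap, b, a); b2 <- ifelse(swap, a, b)
    auc_diff(a2, b2)
  })
  p_perm <- (1 + sum(perm >= obs)) / (1 + nperm)
  expect_lt(abs(res$p_value - p_perm), 0.15)
  expect_error(delong_test(a, b, rep(TRUE, 40)), "both classes")
})

test_that("importance aggregation recovers a scheme with planted signal", {
  set.seed(34)
  n <- 150
  labels <- factor(rep(c("a", "b"), each = n / 2))
  signal <- ifelse(labels == "a", 1, -1)
  X <- cbind(matrix(rnorm(n * 6), n),
             signal + matrix(rnorm(n * 3, sd = 0.4), n),
             matrix(rnorm(n * 4), n))
  prov <- data.frame(scheme = rep(c("S1", "S2", "S3"), c(6, 3, 4)),
                     tag = paste0("f", 1:13))
  rf <- train_rf(X, labels, num_trees = 200, seed = 9)
  agg <- aggregate_importance(rf, prov)
  expect_equal(names(agg$by_scheme)[1], "S2")
  expect_equal(sum(agg$by_scheme), 1)
  expect_setequal(agg$features$tag[1:3], paste0("f", 7:9))
  # a scheme absent from the fitted columns reports 0
  agg2 <- aggregate_importance(rf, prov, all_schemes = c("S1", "S2", "S3", "S4"))
  expect_equal(unname(agg2$by_scheme["S4"]), 0)
  expect_error(aggregate_importance(rf, prov[1:5, ]), "match")
})
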