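test_that("confusion counts classify with OA positive", {
  cm <- confusion(c(rep("OA", 3), rep("HC", 4)), c(rep("OA", 3), rep("HC", 4)))
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 3, tn = 4, fp = 0, fn = 0))
  flipped <- confusion(c("OA", "HC"), c("HC", "OA"))
  expect_equal(flipped$tp + flipped$tn, 0)
  expect_error(confusion(c("OA", "XX"), c("OA", "OA")), "unknown label")
  expect_error(confusion("OA", c("OA", "HC")), "length")
})

test_that("derived metrics agree with naive recomputation on random matrices", {
  set.seed(20)
  for (i in 1:1000) {
    k <- sample(0:30, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    m <- confusion_metrics(confusion_counts(k[1], k[2], k[3], k[4]))
    tp <- k[1]; fp <- k[2]; tn <- k[3]; fn <- k[4]
    expect_equal(m$accuracy_pct, 100 * (tp + tn) / sum(k))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) {
      expect_equal(m$mcc, (tp * tn - fp * fn) / den)
      # MCC is invariant under swapping the positive class
      ms <- confusion_metrics(confusion_counts(tn, fn, tp, fp))
      expect_equal(ms$mcc, m$mcc)
    }
  }
  perfect <- confusion_metrics(confusion_counts(5, 0, 5, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  und <- confusion_metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(und$sensitivity))
  expect_true("sensitivity" %in% und$undefined)
})

test_that("ROC curves are monotone, anchored, and symmetric under reversal", {
  labels <- c(rep("HC", 5), rep("OA", 5))
  sep <- c(runif(5, 0, 0.2), runif(5, 0.8, 1))
  roc <- roc_points(sep, labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))   # passes through (0,1)
  flat <- roc_points(rep(0.5, 10), labels)
  expect_equal(roc_auc(flat), 0.5)
  # reversing scores reflects the curve about the diagonal: AUC complements
  set.seed(77)
  sc <- runif(10)
  expect_equal(roc_auc(roc_points(1 - sc, labels)),
               1 - roc_auc(roc_points(sc, labels)), tolerance = 1e-12)
  expect_error(roc_points(runif(4), rep("OA", 4)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise concordance statistic", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    labels <- c(rep("HC", ceiling(n / 2)), rep("OA", floor(n / 2)))
    scores <- runif(n)
    auc <- roc_auc(roc_points(scores, labels))
    pos <- scores[labels == "OA"]; neg <- scores[labels == "HC"]
    conc <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
    expect_equal(auc, conc, tolerance = 1e-12)
    expect_gte(auc, 0); expect_lte(auc, 1)
  }
  perfect <- roc_points(c(0.05, 0.1, 0.9, 0.95), c("HC", "HC", "OA", "OA"))
  expect_equal(roc_auc(perfect), 1.0)
  # independent library cross-check
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rep(c("HC", "OA"), each = 15)
  scores <- runif(30) + 0.3 * (labels == "OA")
  ours <- roc_auc(roc_points(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("HC", "OA"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the operating threshold maximizes Youden's J with the tie rule", {
  labels <- c(rep("HC", 4), rep("OA", 4))
  scores <- c(0.02, 0.05, 0.08, 0.1, 0.9, 0.92, 0.95, 0.99)
  roc <- roc_points(scores, labels)
  th <- operating_threshold(roc)
  expect_gt(th, 0.1); expect_lte(th, 0.9)
  j_at <- function(t) {
    pred <- ifelse(scores >= t, "OA", "HC")
    m <- confusion_metrics(confusion(labels, pred))
    m$sensitivity + m$specificity - 1
  }
  expect_true(all(j_at(th) >= vapply(scores, j_at, numeric(1))))
  # diagonal ROC: J = 0 everywhere, largest threshold returned
  diag_roc <- roc_points(rep(0.4, 8), labels)
  expect_equal(operating_threshold(diag_roc), 0.4)
})

test_that("reference-study counts reproduce the published derived metrics", {
  ref <- reference_metrics()
  rbf1 <- ref[ref$network == "RBF 9-35-2", ]
  expect_equal(round(rbf1$accuracy_pct, 2), 98.53)
  expect_equal(round(rbf1$mcc, 3), 0.968)
  expect_equal(round(rbf1$f1, 3), 0.979)
})
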