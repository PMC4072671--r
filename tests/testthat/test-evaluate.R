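test_that("confusion counts tally predictions at the threshold", {
  cc <- confusion_counts(c(1, 1, -1, -1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(-2, -3, -1), c(TRUE, TRUE, FALSE))
  expect_equal(cc$TP, 0L)
  expect_equal(cc$FN, 2L)
  # a score exactly at the threshold counts as positive
  cc <- confusion_counts(c(0, -1e-9), c(TRUE, TRUE))
  expect_equal(cc$TP, 1L)
  expect_error(confusion_counts(numeric(0), logical(0)), "empty")
})

test_that("metric formulas match direct arithmetic", {
  perfect <- confusion_counts(c(rep(1, 50), rep(-1, 50)),
                              rep(c(TRUE, FALSE), each = 50))
  m <- classification_metrics(perfect)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
  expect_equal(m$mcc, 1)

  symmetric <- structure(list(TP = 25L, FP = 25L, TN = 25L, FN = 25L),
                         class = "confusion_counts")
  m <- classification_metrics(symmetric)
  expect_equal(m$accuracy, 50)
  expect_equal(m$mcc, 0)

  # TP=60 FN=10 TN=15 FP=15, hand-computed:
  # Sn = 100*60/70, Sp = 100*15/30, Acc = 100*75/100,
  # MCC = (60*15 - 15*10)/sqrt(75*70*30*25) = 750/1984.3135...
  hand <- structure(list(TP = 60L, FP = 15L, TN = 15L, FN = 10L),
                    class = "confusion_counts")
  m <- classification_metrics(hand)
  expect_equal(m$sensitivity, 600 / 7)
  expect_equal(m$specificity, 50)
  expect_equal(m$accuracy, 75)
  expect_equal(m$mcc, 750 / sqrt(75 * 70 * 30 * 25))
})

test_that("metrics agree with brute-force recomputation on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    scores <- rnorm(n)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    t0 <- rnorm(1)
    m <- classification_metrics(confusion_counts(scores, labels, t0))
    pred <- scores >= t0
    expect_equal(m$sensitivity, 100 * mean(pred[labels]))
    expect_equal(m$specificity, 100 * mean(!pred[!labels]))
    expect_equal(m$accuracy, 100 * mean(pred == labels))
    expect_equal(m$coverage, m$sensitivity)
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
  }
})

test_that("MCC is 1 exactly for error-free predictions with both classes present", {
  set.seed(12)
  for (i in 1:10) {
    n_pos <- sample(1:20, 1); n_neg <- sample(1:20, 1)
    cc <- structure(list(TP = n_pos, FP = 0L, TN = n_neg, FN = 0L),
                    class = "confusion_counts")
    expect_equal(classification_metrics(cc)$mcc, 1)
    cc_err <- structure(list(TP = n_pos, FP = 1L, TN = n_neg, FN = 0L),
                        class = "confusion_counts")
    expect_lt(classification_metrics(cc_err)$mcc, 1)
  }
})

test_that("AUC equals the pairwise rank oracle and handles ties", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(300)
  labels <- runif(300) < 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("ROC curve points rise monotonically from (0,0) to (1,1)", {
  set.seed(15)
  r <- roc_auc(rnorm(100), runif(100) < 0.5)
  pts <- r$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("cross-validation plans are stratified, seeded and balanced", {
  labels <- rep(transporter_classes, times = c(12, 11, 30, 10, 12, 11, 20, 40))
  p1 <- cv_plan(labels, seed = 5)
  p2 <- cv_plan(labels, seed = 5)
  expect_identical(p1$fold, p2$fold)
  expect_false(identical(p1$fold, cv_plan(labels, seed = 6)$fold))
  for (cl in transporter_classes) {
    sizes <- table(p1$fold[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_equal(sort(unique(p1$fold)), 1:5)
})

test_that("cross_validate reproduces with a fixed plan and reports per-fold and averaged metrics", {
  ds <- make_dataset(n_per_class = 10, separation = 0.25, seed = 3)
  x <- encode_sequences(ds$sequences, "AAC")
  spec <- svm_spec(gamma = 0.02)
  cv1 <- cross_validate(x, ds$manifest$class_label, spec, seed = 9)
  cv2 <- cross_validate(x, ds$manifest$class_label, spec, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$overall, cv2$overall)
  expect_equal(nrow(cv1$per_class), 8)
  expect_equal(nrow(cv1$folds), 40)  # 8 classes x 5 folds
  expect_equal(cv1$per_class$coverage, cv1$per_class$sensitivity)
  # averaged rows equal the mean of the fold rows
  for (cl in transporter_classes) {
    expect_equal(cv1$per_class$accuracy[cv1$per_class$class == cl],
                 mean(cv1$folds$accuracy[cv1$folds$class == cl]))
  }

  pooled <- cross_validate(x, ds$manifest$class_label, spec, seed = 9,
                           average = "pooled")
  expect_equal(nrow(pooled$per_class), 8)

  expect_error(cross_validate(x[1:30, ], ds$manifest$class_label[1:30], spec),
               "smaller than the fold count")
})

test_that("label-permuted CV accuracy sits at the class-imbalance baseline", {
  ds <- make_dataset(n_per_class = 10, separation = 0.3, seed = 4)
  x <- encode_sequences(ds$sequences, "AAC")
  set.seed(99)
  shuffled <- sample(ds$manifest$class_label)
  cv <- cross_validate(x, shuffled, svm_spec(gamma = 0.02), seed = 4)
  baseline <- 100 * 7 / 8
  sigma <- 100 * sqrt((7 / 8) * (1 / 8) / nrow(x))
  expect_true(all(abs(cv$per_class$accuracy - baseline) <= 3 * sigma))
})

test_that("multi-class confusion matrix rows sum to class sizes", {
  ds <- make_dataset(n_per_class = 10, separation = 0.25, seed = 3)
  x <- encode_sequences(ds$sequences, "AAC")
  fit <- train_ovr(x, ds$manifest$class_label, svm_spec(gamma = 0.02))
  cm <- confusion_matrix_multiclass(fit, x, ds$manifest$class_label)
  expect_equal(dim(cm), c(8L, 8L))
  expect_equal(unname(rowSums(cm)), rep(10, 8))
  expect_equal(sum(cm), 80)
  # strong separation: mass concentrates on the diagonal
  expect_gt(sum(diag(cm)) / sum(cm), 0.9)
})
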