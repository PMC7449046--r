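test_that("confusion matrix matches hand-enumerated example and is additive", {
  truth <- matrix(c(1L, 2L, 1L, 0L), 2, 2) # [[1,1],[2,0]] row-wise
  pred <- matrix(c(1L, 2L, 2L, 0L), 2, 2)  # [[1,2],[2,0]]
  cm <- confusion_matrix(pred, truth)
  expect_equal(cm["leaf", "leaf"], 1)
  expect_equal(cm["leaf", "panicle"], 1)
  expect_equal(cm["panicle", "panicle"], 1)
  expect_equal(cm["background", "background"], 1)
  expect_equal(sum(cm), 4)

  m <- random_masks(11)
  m2 <- random_masks(12)
  joint <- confusion_matrix(cbind(m$pred, m2$pred), cbind(m$truth, m2$truth))
  expect_equal(joint,
               confusion_matrix(m$pred, m$truth) +
                 confusion_matrix(m2$pred, m2$truth))

  expect_error(confusion_matrix(m$pred, m2$truth[1:8, ]), "shape")
  expect_error(confusion_matrix(m$pred + 5L, m$truth), "labels")
})

test_that("identity prediction gives a diagonal confusion and perfect scores", {
  m <- random_masks(3)
  cm <- confusion_matrix(m$truth, m$truth)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(pixel_accuracy(cm), 1)
  expect_equal(mean_iou(cm), 1)
  expect_equal(unname(per_class_accuracy(cm)), c(1, 1, 1))
})

test_that("worked 2x2 example reproduces PA, mIoU and class accuracy", {
  truth <- matrix(c(1L, 2L, 1L, 0L), 2, 2)
  pred <- matrix(c(1L, 2L, 2L, 0L), 2, 2)
  cm <- confusion_matrix(pred, truth)
  expect_equal(pixel_accuracy(cm), 0.75)
  expect_equal(mean_iou(cm), (1 + 0.5 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(unname(per_class_accuracy(cm))[2], 0.5)
})

test_that("metrics agree with brute-force oracles on random mask pairs", {
  for (s in 1:100) {
    m <- random_masks(s)
    cm <- confusion_matrix(m$pred, m$truth)
    expect_equal(cm, oracle_confusion(m$pred, m$truth),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(pixel_accuracy(cm), oracle_pixel_accuracy(m$pred, m$truth),
                 tolerance = 1e-12)
    expect_equal(unname(iou_per_class(cm)), oracle_iou(m$pred, m$truth),
                 tolerance = 1e-12)
    expect_equal(mean_iou(cm), mean(oracle_iou(m$pred, m$truth), na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(unname(per_class_accuracy(cm)),
                 oracle_class_accuracy(m$pred, m$truth), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under pixel permutation", {
  m <- random_masks(42, 12, 12)
  set.seed(9)
  perm <- sample(144)
  cm1 <- confusion_matrix(m$pred, m$truth)
  cm2 <- confusion_matrix(matrix(m$pred[perm], 12), matrix(m$truth[perm], 12))
  expect_equal(cm1, cm2)
})

test_that("degenerate predictors hit the metric boundary values", {
  truth <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  allbg <- matrix(0L, 2, 2)
  cm <- confusion_matrix(allbg, truth)
  pca <- per_class_accuracy(cm)
  expect_equal(unname(pca), c(1, 0, 0))
  ## every pixel wrong
  cm2 <- confusion_matrix(matrix(1L, 2, 2), matrix(0L, 2, 2))
  expect_equal(pixel_accuracy(cm2), 0)
  expect_error(pixel_accuracy(matrix(0, 3, 3)), "empty")
})

test_that("AUC matches the pair-counting oracle and handles ties", {
  ## 10-pixel hand-built example per class
  set.seed(5)
  truth <- matrix(sample(0:2, 10, TRUE), 2, 5)
  pm <- array(runif(30), c(2, 5, 3))
  pm[1, 1, ] <- c(0.4, 0.4, 0.2) # inject ties
  r <- roc_auc(list(pm), list(truth))
  for (k in 1:3) {
    ora <- oracle_auc(as.vector(pm[, , k]), as.vector(truth) == k - 1)
    expect_equal(unname(r$auc_per_class[k]), ora, tolerance = 1e-12)
  }
  ## identical scores for all pixels -> 0.5 by midpoint convention
  pm2 <- array(1 / 3, c(2, 5, 3))
  r2 <- roc_auc(list(pm2), list(truth))
  expect_equal(unname(r2$auc_per_class), rep(0.5, 3))
  ## one-hot probabilities on truth -> AUC 1 per class
  pm3 <- array(0, c(2, 5, 3))
  for (k in 1:3) pm3[, , k] <- (truth == k - 1) * 1
  r3 <- roc_auc(list(pm3), list(truth))
  expect_equal(unname(r3$auc_per_class), rep(1, 3))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  truth <- matrix(sample(0:2, 400, TRUE, prob = c(0.5, 0.3, 0.2)), 20, 20)
  pm <- array(runif(1200), c(20, 20, 3))
  pm[, , 2] <- pm[, , 2] + (truth == 1) # informative leaf channel
  r <- roc_auc(list(pm), list(truth))
  for (k in 1:3) {
    ref <- as.numeric(pROC::auc(
      pROC::roc(as.vector(truth) == k - 1, as.vector(pm[, , k]),
                quiet = TRUE, direction = "<")))
    expect_equal(unname(r$auc_per_class[k]), ref, tolerance = 1e-10)
  }
})

test_that("absent classes are excluded from macro AUC and flagged NA", {
  truth <- matrix(c(0L, 1L, 0L, 1L), 2, 2) # no panicle pixels
  pm <- array(runif(12), c(2, 2, 3))
  r <- roc_auc(list(pm), list(truth))
  expect_true(is.na(r$auc_per_class["panicle"]))
  expect_equal(r$auc_macro, mean(r$auc_per_class[1:2]))
})

test_that("evaluate_masks pools images and reports a coherent summary", {
  ms <- lapply(1:4, function(s) random_masks(s))
  preds <- lapply(ms, `[[`, "pred")
  truths <- lapply(ms, `[[`, "truth")
  rep_ <- evaluate_masks(preds, truths)
  pooled <- Reduce(`+`, Map(confusion_matrix, preds, truths))
  expect_equal(rep_$confusion, pooled)
  expect_equal(rep_$mean_iou, mean(iou_per_class(pooled), na.rm = TRUE))
  ## PA lies between the extreme per-class accuracies
  pca <- rep_$per_class_accuracy
  expect_gte(rep_$pixel_accuracy, min(pca, na.rm = TRUE))
  expect_lte(rep_$pixel_accuracy, max(pca, na.rm = TRUE))
  ## mIoU bounded by the best per-class IoU
  expect_lte(rep_$mean_iou, max(rep_$iou_per_class, na.rm = TRUE))
})
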