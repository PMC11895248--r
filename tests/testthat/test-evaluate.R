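# the 4x4 fixture: truth and prediction each mark 4 pixels, overlapping in 2
fixture_4x4 <- function() {
  truth <- matrix(0, 4, 4); truth[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 3:4] <- 1; pred[2, 1:2] <- 1
  list(pred = pred, truth = truth)
}

test_that("confusion counts are exact pixel tallies", {
  ones <- matrix(1, 10, 10)
  c1 <- confusion_counts(ones, ones)
  expect_equal(c1, list(TP = 100L, TN = 0L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  c2 <- confusion_counts(1 - ones, ones)
  expect_equal(c2$TP, 0); expect_equal(c2$TN, 0)
  f <- fixture_4x4()
  cc <- confusion_counts(f$pred, f$truth)
  expect_equal(cc, list(TP = 2L, TN = 10L, FP = 2L, FN = 2L),
               ignore_attr = TRUE)
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)),
               "binary")
})

test_that("accuracy, dice and iou agree with the enumerated fixture", {
  f <- fixture_4x4()
  cc <- confusion_counts(f$pred, f$truth)
  expect_equal(pixel_accuracy(cc), 12 / 16)
  expect_equal(dice_coef(f$pred, f$truth), 0.5)
  expect_equal(iou_coef(f$pred, f$truth), 1 / 3)
  # algebraic identity on the same pair
  expect_equal(2 * (1 / 3) / (1 + 1 / 3), 0.5)
})

test_that("dice equals 2 iou / (1 + iou) on random mask pairs", {
  set.seed(30)
  for (i in 1:1000) {
    a <- matrix(rbinom(25, 1, runif(1, 0.05, 0.8)), 5, 5)
    b <- matrix(rbinom(25, 1, runif(1, 0.05, 0.8)), 5, 5)
    d <- dice_coef(a, b); j <- iou_coef(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
  }
})

test_that("the precision-sensitivity form of Dice equals the overlap form", {
  set.seed(31)
  for (i in 1:50) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    cc <- confusion_counts(a, b)
    if (cc$TP == 0) next
    precision <- cc$TP / (cc$TP + cc$FP)
    sensitivity <- cc$TP / (cc$TP + cc$FN)
    expect_equal(2 * precision * sensitivity / (precision + sensitivity),
                 dice_coef(a, b), tolerance = 1e-12)
  }
})

test_that("empty-vs-empty masks score 1, disjoint masks score 0", {
  z <- matrix(0, 3, 3)
  expect_equal(dice_coef(z, z), 1)
  expect_equal(iou_coef(z, z), 1)
  a <- z; a[1, 1] <- 1
  b <- z; b[3, 3] <- 1
  expect_equal(dice_coef(a, b), 0)
  expect_equal(iou_coef(a, b), 0)
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  truth <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.4, 0.6, 0.2, 0.1)
  r <- roc_auc(scores, truth)
  expect_equal(r$auc, oracle_auc_pairs(scores, truth), tolerance = 1e-12)
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0 || sum(truth) == n) next
    scores <- runif(n)   # continuous, ties almost surely absent
    expect_equal(roc_auc(scores, truth)$auc, oracle_auc_pairs(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  truth <- rbinom(200, 1, 0.3)
  scores <- runif(200) + truth * 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-10)
})

test_that("degenerate ROC cases behave as defined", {
  truth <- c(1, 1, 0, 0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), truth)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 4), truth)$auc, 0.5)
  expect_error(roc_auc(runif(4), c(1, 1, 1, 1)), "single class")
})

test_that("metrics are invariant under simultaneous pixel permutation", {
  set.seed(34)
  pred <- matrix(rbinom(100, 1, 0.3), 10, 10)
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  perm <- sample(100)
  expect_equal(dice_coef(pred[perm], truth[perm]), dice_coef(pred, truth))
  expect_equal(iou_coef(pred[perm], truth[perm]), iou_coef(pred, truth))
  expect_equal(confusion_counts(pred[perm], truth[perm]),
               confusion_counts(pred, truth))
})

test_that("class imbalance inflates accuracy while Dice exposes failure", {
  set.seed(35)
  truth <- matrix(0, 100, 100)
  truth[sample(1e4, 50)] <- 1   # 0.5% lesion pixels
  all_bg <- matrix(0, 100, 100)
  cc <- confusion_counts(all_bg, truth)
  expect_gte(pixel_accuracy(cc), 0.995)
  expect_equal(dice_coef(all_bg, truth), 0)
})

test_that("aggregated evaluation and JSON round-trip work end to end", {
  set.seed(36)
  truths <- replicate(3, matrix(rbinom(64, 1, 0.2), 8, 8), simplify = FALSE)
  # the oracle model: probabilities equal to the truth
  probs <- lapply(truths, function(t) t * 0.98 + 0.01)
  mt <- evaluate_predictions(probs, truths)
  expect_equal(mt$dice, 1); expect_equal(mt$iou, 1)
  expect_equal(mt$accuracy, 1); expect_equal(mt$auc, 1)
  expect_equal(nrow(mt$per_image), 3)
  path <- withr::local_tempfile(fileext = ".json")
  metrics_to_json(mt, path)
  back <- metrics_from_json(path)
  expect_equal(back$dice, mt$dice)
  expect_equal(back$counts$TP, mt$counts$TP)
  expect_equal(back$per_image$iou, mt$per_image$iou)
})

test_that("random scores give chance-level AUC on balanced masks", {
  set.seed(37)
  aucs <- vapply(1:20, function(i) {
    truth <- matrix(rbinom(400, 1, 0.5), 20, 20)
    probs <- matrix(runif(400), 20, 20)
    evaluate_predictions(list(probs), list(truth))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
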