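test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  mw_auc <- function(pos, neg) {
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(roc_curve(c(0.9, 0.8), c(0.2, 0.1))$auc, 1)
  expect_equal(roc_curve(c(0.3, 0.7), c(0.3, 0.7))$auc, 0.5)
  expect_equal(roc_curve(0.6, 0.6)$auc, 0.5)   # ties split
  set.seed(77)
  for (r in 1:25) {
    pos <- round(runif(sample(3:40, 1)), 2)  # rounding forces ties
    neg <- round(runif(sample(3:40, 1)), 2)
    expect_equal(roc_curve(pos, neg)$auc, mw_auc(pos, neg),
                 tolerance = 1e-9)
  }
})

test_that("ROC curves are monotone with proper endpoints", {
  set.seed(8)
  curve <- roc_curve(runif(50, 0.4, 1), runif(50, 0, 0.6))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_equal(c(tail(curve$fpr, 1), tail(curve$tpr, 1)), c(1, 1))
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("threshold selection honors both criteria", {
  curve <- roc_curve(c(0.9, 0.8), c(0.2, 0.1))
  thr <- choose_threshold(curve, target_fpr = 0.05)
  expect_gte(thr, 0.3)        # inside the separating gap
  expect_lte(thr, 0.8)
  expect_equal(mean(c(0.2, 0.1) >= thr), 0)
  # target_fpr 1 accepts everything
  thr_all <- choose_threshold(curve, target_fpr = 1)
  expect_true(all(c(0.9, 0.8, 0.2, 0.1) >= thr_all))
  # F-score criterion lands in the gap on separable scores
  thr_f <- choose_threshold(curve, max_fscore = TRUE)
  expect_gte(mean(c(0.9, 0.8) >= thr_f), 1)
  expect_equal(mean(c(0.2, 0.1) >= thr_f), 0)
  # impossible target degenerates to reject-all with a warning
  tied <- roc_curve(c(0.5, 0.5), c(0.5, 0.5))
  expect_warning(thr_d <- choose_threshold(tied, target_fpr = 0.01),
                 "reject-all")
  expect_gt(thr_d, 0.5)
})

test_that("rejection thresholding labels and accepts correctly", {
  fit <- tiny_fit()
  te <- tiny_split()$test
  preds <- predict_with_rejection(fit, te, threshold = 0)
  expect_true(all(preds$accepted))
  expect_false(any(preds$class == "rejected"))
  preds2 <- predict_with_rejection(fit, te, threshold = 1.01)
  expect_true(all(!preds2$accepted))
  expect_true(all(preds2$class == "rejected"))
  # accept at equality
  thr <- preds$max_prob[1]
  p3 <- predict_with_rejection(fit, te, threshold = thr)
  expect_true(p3$accepted[1])
  # stored default threshold matches the shipped value
  expect_equal(fit$threshold, 0.977)
})

test_that("in-family confidence dominates shuffled-decoy confidence", {
  fit <- tiny_fit()
  te <- tiny_split()$test
  pos <- max_softmax_scores(fit, te)$max_prob
  shuf <- make_ood("shuffle", reference = tiny_benchmark()$dataset$sequences,
                   n = 40L, seed = 33L)
  enc_neg <- encode_dataset(as_decoy_dataset(shuf), "onehot", L = 48L)
  neg <- max_softmax_scores(fit, enc_neg)$max_prob
  expect_gt(median(pos), median(neg))
  expect_gt(roc_curve(pos, neg)$auc, 0.8)
})

test_that("score and ROC tables serialize to the TSV dialects", {
  fit <- tiny_fit()
  preds <- predict_with_rejection(fit, tiny_split()$test, threshold = 0.5)
  f <- tempfile()
  write_scores_tsv(preds, f)
  back <- read.table(f, sep = "\t")
  expect_equal(nrow(back), nrow(preds))
  expect_equal(back$V3, preds$max_prob, tolerance = 1e-6)
  curve <- roc_curve(c(0.9, 0.8), c(0.2, 0.1))
  f2 <- tempfile()
  write_roc_tsv(curve, f2)
  expect_equal(nrow(read.table(f2, sep = "\t")), length(curve$thresholds))
})
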