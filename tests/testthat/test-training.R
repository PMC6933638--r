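test_that("separable synthetic families are learned to high accuracy", {
  fit <- tiny_fit()
  rep_te <- evaluate_cnn(fit, tiny_split()$test)
  expect_gte(rep_te$accuracy, 0.98)
  # optimization sanity: training data essentially memorized
  rep_tr <- evaluate_cnn(fit, tiny_split()$train)
  expect_gte(rep_tr$accuracy, 0.99)
  expect_true(all(diff(range(fit$history)) > 0))
})

test_that("training is deterministic under a fixed seed", {
  tr <- tiny_split()$train
  cfg <- train_config(epochs = 2L, seed = 9L)
  f1 <- train_cnn(tr, config = cfg)
  f2 <- train_cnn(tr, config = cfg)
  expect_equal(tail(f1$history, 1), tail(f2$history, 1), tolerance = 1e-6)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("degenerate training inputs are rejected", {
  enc <- tiny_split()$enc
  one_class <- hairpinCNN:::subset_encoded(enc, enc$labels == 0L)
  one_class$label_index <- enc$label_index["fam01"]
  expect_error(train_cnn(one_class), "two classes")
  bad_spec <- onehot_cnn_spec(classes = 5L, input_len = enc$L)
  expect_error(train_cnn(enc, spec = bad_spec), "classes")
  struct_spec <- struct_cnn_spec(classes = 2L, input_len = enc$L)
  expect_error(train_cnn(enc, spec = struct_spec), "disagree")
})

test_that("evaluation metrics follow the confusion-matrix definitions", {
  lm <- c(a = 0L, b = 1L)
  # 9 of 10 correct -> accuracy 0.9; class a: TP 5, FP 1, FN 0
  rep1 <- hairpinCNN:::eval_report(truth = c(rep(0L, 5), rep(1L, 5)),
                                   pred = c(rep(0L, 5), 0L, rep(1L, 4)),
                                   label_map = lm)
  expect_equal(rep1$accuracy, 0.9)
  a <- rep1$per_class[rep1$per_class$family == "a", ]
  expect_equal(a$precision, 5 / 6)
  expect_equal(a$recall, 1)
  expect_equal(a$fscore, 2 * (5 / 6) / (1 + 5 / 6))

  # never-predicted class: precision, recall and F default to 0
  rep2 <- hairpinCNN:::eval_report(truth = c(0L, 1L), pred = c(0L, 0L),
                                   label_map = lm)
  b <- rep2$per_class[rep2$per_class$family == "b", ]
  expect_equal(c(b$precision, b$recall, b$fscore), c(0, 0, 0))

  # macro F-score is 1 iff the confusion matrix is diagonal
  rep3 <- hairpinCNN:::eval_report(truth = c(0L, 1L), pred = c(0L, 1L),
                                   label_map = lm)
  expect_equal(rep3$macro_fscore, 1)
  expect_true(rep2$macro_fscore >= 0 && rep2$macro_fscore <= 1)
})

test_that("softmax predictions are proper distributions", {
  S <- predict_softmax(tiny_fit(), tiny_split()$test)
  expect_equal(unname(rowSums(S)), rep(1, nrow(S)), tolerance = 1e-6)
  expect_true(all(S >= 0))
  expect_equal(colnames(S), names(tiny_split()$enc$label_index))
})

test_that("stratified folds partition every class evenly", {
  labels <- rep(0:2, c(100L, 55L, 12L))
  folds <- hairpinCNN:::stratified_folds(labels, 5L, seed = 4L)
  expect_setequal(unique(folds), 1:5)
  for (c0 in 0:2) {
    per_fold <- table(folds[labels == c0])
    expect_lte(diff(range(per_fold)), 1L)  # within +-1 sequence
  }
  # 100 per class with k = 5 gives exactly 80 train / 20 test per class
  expect_true(all(table(folds[labels == 0L]) == 20L))
  expect_error(hairpinCNN:::stratified_folds(rep(0:1, c(3L, 10L)), 5L),
               "fewer than")
})

test_that("cross-validation folds are disjoint and exhaustive", {
  enc <- tiny_split()$enc
  reports <- kfold_cv(enc, k = 2L,
                      config = train_config(epochs = 2L, seed = 3L))
  expect_length(reports, 2L)
  folds <- attr(reports, "folds")
  expect_equal(sort(unique(folds)), 1:2)
  expect_length(folds, length(enc$labels))
  expect_error(kfold_cv(enc, k = 1L), "at least 2")
})
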