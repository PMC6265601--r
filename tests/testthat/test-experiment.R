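# Cross-validation bookkeeping, balancing, classifiers, accuracy identities.

test_that("stratified folds partition all users with near-equal class counts", {
  labels <- rep(c("low", "high"), c(611, 171))
  folds <- stratified_kfold(labels, 5, seed = 3)
  expect_equal(sort(unlist(folds)), 1:782)
  expect_equal(sum(vapply(folds, length, integer(1))), 782)
  for (f in folds) {
    expect_true(abs(sum(labels[f] == "low") - 611 / 5) <= 1)
    expect_true(abs(sum(labels[f] == "high") - 171 / 5) <= 1)
  }
  expect_identical(folds, stratified_kfold(labels, 5, seed = 3))
  expect_false(identical(folds, stratified_kfold(labels, 5, seed = 4)))
  expect_error(stratified_kfold(rep(c("low", "high"), c(50, 3)), 5),
               "fewer than k")
})

test_that("balancing keeps the minority whole and equalizes class sizes", {
  labels <- rep(c("low", "high"), c(611, 171))
  train_idx <- seq_len(625)  # 488 low + 137 high, a 4/5 training split
  labels_train <- rep(c("low", "high"), c(488, 137))
  labels_all <- c(labels_train, rep("low", 50))
  bal <- balance_training(train_idx, labels_all, seed = 5)
  expect_equal(sum(labels_all[bal] == "low"), 137)
  expect_equal(sum(labels_all[bal] == "high"), 137)
  expect_true(all(bal %in% train_idx))
  expect_identical(bal, balance_training(train_idx, labels_all, seed = 5))
  # already balanced: unchanged up to order
  even <- balance_training(1:20, rep(c("low", "high"), 10), seed = 1)
  expect_equal(sort(even), 1:20)
})

test_that("all four methods separate a linearly separable toy set", {
  withr::with_seed(11, {
    x_tr <- rbind(matrix(rnorm(20, -2, 0.3), 10), matrix(rnorm(20, 2, 0.3), 10))
    x_te <- rbind(matrix(rnorm(12, -2, 0.3), 6), matrix(rnorm(12, 2, 0.3), 6))
  })
  colnames(x_tr) <- colnames(x_te) <- c("f1", "f2")
  y_tr <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  y_te <- rep(c("low", "high"), each = 6)
  for (m in c("ridge_logistic", "lasso_logistic", "random_forest", "svm_rbf")) {
    spec <- experiment_spec(m, seed = 2)
    # glmnet warns about the deliberately tiny class sizes; not under test
    pred <- suppressWarnings(fit_predict(spec, x_tr, y_tr, x_te, seed = 2))
    expect_equal(as.character(pred), y_te, label = m)
  }
})

test_that("degenerate fits are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(fit_predict(experiment_spec("ridge_logistic"), x,
                           factor(rep("low", 10), levels = c("low", "high")),
                           x), "single class")
  expect_error(experiment_spec("boosted_trees"), "arg")
})

test_that("overall accuracy is the label-frequency-weighted mean of class accuracies", {
  fm <- demo_features()
  labels <- demo_pipeline()$cls$outcome_labels
  res <- run_experiment(fm, labels,
                        experiment_spec("lasso_logistic", balanced = TRUE,
                                        n_subsamples = 2, seed = 9))
  n_low <- sum(labels == "low"); n_high <- sum(labels == "high")
  for (i in seq_len(nrow(res$table))) {
    row <- res$table[i, ]
    expect_equal(row$acc_overall,
                 (row$acc_low * n_low + row$acc_high * n_high) / (n_low + n_high))
    expect_equal(row$tp + row$tn + row$fp + row$fn, n_low + n_high)
  }
  # each user predicted exactly once per subsample
  per_user <- table(res$predictions$user_id, res$predictions$subsample)
  expect_true(all(per_user == 1))
})

test_that("a fixed spec and data give identical results on re-run", {
  fm <- demo_features()
  labels <- demo_pipeline()$cls$outcome_labels
  spec <- experiment_spec("random_forest", balanced = TRUE, n_subsamples = 2,
                          seed = 17)
  r1 <- run_experiment(fm, labels, spec)
  r2 <- run_experiment(fm, labels, spec)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("a 2-fold run on a 20-user toy cohort completes quickly", {
  fm <- demo_features()[1:20, ]
  labels <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  names(labels) <- fm$user_id
  elapsed <- system.time({
    res <- run_experiment(fm, labels, experiment_spec("random_forest",
                                                      k_folds = 2, seed = 1))
  })["elapsed"]
  expect_equal(nrow(res$table), 1)
  expect_false(anyNA(res$predictions$pred))
  expect_lt(elapsed, 5)
})
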