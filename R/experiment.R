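# Prediction experiments: four classifiers (ridge and LASSO logistic
# regression, random forest, RBF-kernel SVM), stratified k-fold
# cross-validation, and optional random subsampling of the majority class in
# each training fold to counter class imbalance. Performance is reported as
# per-class and overall accuracy with high volatility as the positive class.
#
# Leakage discipline: fold membership is fixed up front; balancing,
# standardization and penalty selection all see training-fold rows only.

EXPERIMENT_METHODS <- c("ridge_logistic", "lasso_logistic", "random_forest",
                        "svm_rbf")

#' Experiment specification
#'
#' @param method One of `"ridge_logistic"`, `"lasso_logistic"`,
#'   `"random_forest"`, `"svm_rbf"`.
#' @param balanced Balance each training fold by majority-class subsampling?
#' @param n_subsamples Number of independent majority subsamples when
#'   `balanced` (default 3).
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling folds, subsamples and model fitting.
#' @param rf_n_trees Random-forest tree count (default 100).
#' @param rf_mtry Features tried per split; default `round(2 * sqrt(130))`
#'   = 23, two-times-root-n on the 130 canonical features (capped at the
#'   encoded column count at fit time).
#' @param svm_cost,svm_gamma Optional SVM cost and RBF width; `NULL` uses the
#'   library defaults (cost 1, gamma 1/ncol).
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(method, balanced = FALSE, n_subsamples = 3L,
                            k_folds = 5L, seed = 1L, rf_n_trees = 100L,
                            rf_mtry = round(2 * sqrt(130)),
                            svm_cost = NULL, svm_gamma = NULL) {
  method <- match.arg(method, EXPERIMENT_METHODS)
  if (k_folds < 2) stop("k_folds must be at least 2")
  if (balanced && n_subsamples < 1) stop("n_subsamples must be >= 1 when balanced")
  structure(list(method = method, balanced = balanced,
                 n_subsamples = as.integer(n_subsamples),
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_mtry = as.integer(rf_mtry),
                 svm_cost = svm_cost, svm_gamma = svm_gamma),
            class = "experiment_spec")
}

#' Stratified k-fold test sets
#'
#' Partitions indices into k folds so that each class is split as evenly as
#' possible: per-fold class counts differ from the exact class-proportional
#' count by at most one member, and each index is tested exactly once.
#'
#' @param labels Factor/character class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffles.
#' @return List of k integer vectors (test indices), pairwise disjoint, whose
#'   union is `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  small <- table(labels) < k
  if (any(small)) {
    stop("class '", names(which(small))[1], "' has fewer than k members")
  }
  withr::with_seed(seed, {
    folds <- rep(list(integer(0)), k)
    for (cls in levels(labels)) {
      idx <- sample(which(labels == cls))
      assignment <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assignment == f])
    }
    lapply(folds, sort)
  })
}

#' Balance a training set by majority-class subsampling
#'
#' Keeps the minority class whole and samples the majority class down to the
#' minority size, without replacement. Test indices are never touched.
#'
#' @param train_idx Integer vector of training indices.
#' @param labels Full label vector (indexed by `train_idx`).
#' @param seed Integer seed.
#' @return Sorted integer vector of balanced training indices.
#' @export
balance_training <- function(train_idx, labels, seed = 1L) {
  lab <- as.factor(labels)[train_idx]
  tab <- table(lab)
  if (length(tab) != 2) stop("balancing requires exactly two classes present")
  minority <- names(which.min(tab))
  majority <- setdiff(names(tab), minority)
  keep_min <- train_idx[lab == minority]
  maj_pool <- train_idx[lab == majority]
  keep_maj <- withr::with_seed(seed, sample(maj_pool, length(keep_min)))
  sort(c(keep_min, keep_maj))
}

#' One-hot encode a canonical feature matrix
#'
#' Expands the categorical columns into dummy indicators (full dummy coding
#' against fixed schema levels, so the encoding does not depend on which rows
#' are present) and returns a numeric matrix.
#'
#' @param features Feature tibble from [extract_feature_matrix()] (with
#'   `user_id` column).
#' @return Numeric matrix, rownames = user ids.
#' @export
encode_features <- function(features) {
  schema <- feature_schema()
  cols <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- features[[nm]]
    if (schema$type[i] == "categorical") {
      lev <- schema$levels[[i]]
      x <- factor(as.character(x), levels = lev)
      for (l in lev[-1]) {  # first level is the reference
        cols[[paste0(nm, "=", l)]] <- as.numeric(x == l)
      }
    } else {
      cols[[nm]] <- as.numeric(x)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- features$user_id
  mat
}

standardize_train_test <- function(x_train, x_test) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(train = scale(x_train, center = ctr, scale = scl),
       test = scale(x_test, center = ctr, scale = scl))
}

#' Fit one classifier and predict test labels
#'
#' Continuous features are standardized on the training rows only. Ridge and
#' LASSO penalty strengths are chosen by internal cross-validation on the
#' training data (one-standard-error rule); the random forest uses
#' `rf_n_trees` trees and `rf_mtry` candidate features per split; the SVM
#' uses an RBF kernel with library-default cost and width unless configured.
#'
#' @param spec An [experiment_spec()].
#' @param x_train,x_test Numeric matrices from [encode_features()].
#' @param y_train Factor with levels `low`/`high`.
#' @param seed Integer seed for the stochastic fitting steps.
#' @return Factor of predicted test labels (levels `low`/`high`).
#' @export
fit_predict <- function(spec, x_train, y_train, x_test, seed = spec$seed) {
  y_train <- factor(y_train, levels = c("low", "high"))
  if (length(unique(y_train)) < 2) stop("training set contains a single class")
  std <- standardize_train_test(x_train, x_test)
  xtr <- std$train; xte <- std$test
  pred <- withr::with_seed(seed, switch(
    spec$method,
    ridge_logistic = ,
    lasso_logistic = {
      alpha <- if (spec$method == "ridge_logistic") 0 else 1
      # keep >= 3 observations per internal-CV fold on small training sets
      nfolds <- max(3L, min(10L, floor(length(y_train) / 3),
                            min(table(y_train))))
      fit <- glmnet::cv.glmnet(xtr, y_train, family = "binomial",
                               alpha = alpha, nfolds = nfolds,
                               standardize = FALSE)
      as.character(stats::predict(fit, newx = xte, s = "lambda.1se",
                                  type = "class"))
    },
    random_forest = {
      fit <- randomForest::randomForest(
        x = xtr, y = y_train, ntree = spec$rf_n_trees,
        mtry = min(spec$rf_mtry, ncol(xtr)))
      as.character(stats::predict(fit, xte))
    },
    svm_rbf = {
      args <- list(x = xtr, y = y_train, kernel = "radial", scale = FALSE)
      if (!is.null(spec$svm_cost)) args$cost <- spec$svm_cost
      if (!is.null(spec$svm_gamma)) args$gamma <- spec$svm_gamma
      fit <- do.call(e1071::svm, args)
      as.character(stats::predict(fit, xte))
    },
    stop("unknown method: ", spec$method)
  ))
  factor(pred, levels = c("low", "high"))
}

accuracy_row <- function(truth, pred) {
  truth <- factor(truth, levels = c("low", "high"))
  pred <- factor(pred, levels = c("low", "high"))
  tp <- sum(truth == "high" & pred == "high")
  tn <- sum(truth == "low" & pred == "low")
  fp <- sum(truth == "low" & pred == "high")
  fn <- sum(truth == "high" & pred == "low")
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc_low = 100 * tn / (tn + fp),
    acc_high = 100 * tp / (tp + fn),
    acc_overall = 100 * (tp + tn) / length(truth)
  )
}

#' Run a cross-validated prediction experiment
#'
#' Runs stratified k-fold cross-validation for one method. In unbalanced
#' mode a single pass is made over the folds; in balanced mode the folds are
#' held fixed and `n_subsamples` passes are made, each drawing a fresh
#' majority subsample inside every training fold, so that subsample-to-
#' subsample variation is isolated from fold variation.
#'
#' @param features Feature tibble (`user_id` + 130 canonical columns).
#' @param labels Class labels (`low`/`high`), either aligned with the rows of
#'   `features` or named by user id.
#' @param spec An [experiment_spec()].
#' @return An `experiment_result`: list with `table` (one row per subsample:
#'   confusion counts and the three accuracy percentages), `predictions`
#'   (per-user predictions with fold and subsample ids) and `spec`.
#' @export
run_experiment <- function(features, labels, spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (!is.null(names(labels))) labels <- labels[features$user_id]
  y <- factor(as.character(labels), levels = c("low", "high"))
  if (anyNA(y)) stop("labels missing or not 'low'/'high' for some users")
  x <- encode_features(features)
  folds <- stratified_kfold(y, spec$k_folds, seed = spec$seed)
  n_pass <- if (spec$balanced) spec$n_subsamples else 1L
  seeds <- withr::with_seed(spec$seed,
                            matrix(sample.int(.Machine$integer.max,
                                              2 * n_pass * spec$k_folds),
                                   nrow = 2))
  rows <- vector("list", n_pass)
  pred_rows <- vector("list", n_pass)
  for (r in seq_len(n_pass)) {
    pred <- factor(rep(NA_character_, length(y)), levels = c("low", "high"))
    fold_id <- integer(length(y))
    for (f in seq_len(spec$k_folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_along(y), test_idx)
      scol <- (r - 1) * spec$k_folds + f
      if (spec$balanced) {
        train_idx <- balance_training(train_idx, y, seed = seeds[1, scol])
      }
      pred[test_idx] <- fit_predict(spec, x[train_idx, , drop = FALSE],
                                    y[train_idx], x[test_idx, , drop = FALSE],
                                    seed = seeds[2, scol])
      fold_id[test_idx] <- f
    }
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(method = spec$method,
                     subsample = if (spec$balanced) r else NA_integer_),
      accuracy_row(y, pred)
    )
    pred_rows[[r]] <- tibble::tibble(
      user_id = features$user_id,
      subsample = if (spec$balanced) r else NA_integer_,
      fold = fold_id, truth = y, pred = pred
    )
  }
  out <- list(table = dplyr::bind_rows(rows),
              predictions = dplyr::bind_rows(pred_rows), spec = spec)
  class(out) <- "experiment_result"
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %s (%s)\n", x$spec$method,
              if (x$spec$balanced) "balanced training" else "original class mix"))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run several methods under a shared protocol
#'
#' Convenience wrapper mirroring the published experiment layout: same
#' folds, same subsamples per method.
#'
#' @param features,labels As in [run_experiment()].
#' @param methods Methods to run (default all four).
#' @param balanced,n_subsamples,k_folds,seed Shared protocol settings.
#' @param ... Further arguments to [experiment_spec()].
#' @return Tibble binding the per-method result tables.
#' @export
run_methods <- function(features, labels, methods = EXPERIMENT_METHODS,
                        balanced = FALSE, n_subsamples = 3L, k_folds = 5L,
                        seed = 1L, ...) {
  res <- lapply(methods, function(m) {
    spec <- experiment_spec(m, balanced = balanced, n_subsamples = n_subsamples,
                            k_folds = k_folds, seed = seed, ...)
    run_experiment(features, labels, spec)$table
  })
  dplyr::bind_rows(res)
}
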