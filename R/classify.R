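# Cross-validated classification of patch feature vectors.
#
# Three model families, standard fits behind one surface: a decision tree
# (rpart), an RBF-kernel support vector machine (e1071) and an L2-penalized
# (ridge) logistic regression (glmnet). Confusion counts are pooled over the
# folds before computing metrics (micro-average); "scar" is the positive
# class throughout.

MODEL_NAMES <- c("decision_tree", "svm", "logistic_regression")

#' Stratified k-fold partition
#'
#' Splits indices into `k` disjoint folds preserving class proportions: each
#' class's indices are shuffled with the seed and dealt round-robin, so per-
#' fold class counts differ by at most 1 from perfect proportionality.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors partitioning `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) rs_stop("radonscar_bad_folds", "k must be >= 2")
  tab <- table(labels)
  if (any(tab < k)) {
    rs_stop("radonscar_class_too_small",
            "every class needs >= k members; smallest has %d", min(tab))
  }
  folds <- vector("list", k)
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assignment == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param counts A list or named vector with `tp`, `fp`, `tn`, `fn`
#'   (positive class = scar).
#' @return Named list with `sensitivity` = tp/(tp+fn), `specificity` =
#'   tn/(tn+fp), `accuracy` = (tp+tn)/total.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fn == 0 || tn + fp == 0) {
    rs_stop("radonscar_undefined_metric",
            "sensitivity/specificity undefined: one class has no samples")
  }
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn)
  )
}

fit_and_predict <- function(model, train_x, train_y, test_x, hyper) {
  if (model == "decision_tree") {
    df <- data.frame(train_x, y = train_y)
    # balanced priors stand in for balanced class weights
    fit <- rpart::rpart(
      y ~ ., data = df, method = "class",
      parms = list(prior = c(0.5, 0.5)),
      control = rpart::rpart.control(
        maxdepth = hyper$tree_max_depth, minsplit = hyper$tree_min_split,
        minbucket = hyper$tree_min_leaf, cp = hyper$tree_cp, xval = 0
      )
    )
    as.character(predict(fit, data.frame(test_x), type = "class"))
  } else if (model == "svm") {
    fit <- e1071::svm(train_x, train_y, kernel = "radial",
                      cost = hyper$svm_cost, gamma = hyper$svm_gamma,
                      scale = FALSE)
    as.character(predict(fit, test_x))
  } else {
    fit <- glmnet::glmnet(train_x, train_y, family = "binomial",
                          alpha = 0, lambda = hyper$logreg_lambda)
    prob <- predict(fit, test_x, type = "response")[, 1]
    ifelse(prob > 0.5, levels(train_y)[2], levels(train_y)[1])
  }
}

default_hyper <- function() {
  list(
    tree_max_depth = 30L,   # rpart's maximum; effectively unlimited
    tree_min_split = 2L,
    tree_min_leaf = 1L,
    tree_cp = 0,
    svm_cost = 1,
    svm_gamma = 0.1,        # 1 / n_features
    logreg_lambda = 0.01
  )
}

#' Cross-validated evaluation of the three classifiers
#'
#' For each requested model family: fit on k-1 folds, predict the held-out
#' fold, pool the confusion counts over folds, and compute sensitivity,
#' specificity and accuracy from the pooled counts.
#'
#' @param features Feature data frame (`label` plus `f0`..`f9`), e.g. from
#'   [patch_features()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold shuffle.
#' @param models Subset of `c("decision_tree", "svm", "logistic_regression")`.
#' @param hyper Named list overriding entries of the default hyperparameters
#'   (`tree_max_depth`, `tree_min_split`, `tree_min_leaf`, `tree_cp`,
#'   `svm_cost`, `svm_gamma`, `logreg_lambda`).
#' @return Named list of evaluation reports, one per model: `model`, the
#'   three metrics, `folds`, `seed`, pooled `counts`, and `per_fold` counts.
#' @export
run_models <- function(features, k = 5, seed = 1L, models = MODEL_NAMES,
                       hyper = list()) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  hy <- utils::modifyList(default_hyper(), hyper)
  x <- as.matrix(features[, paste0("f", 0:9)])
  y <- factor(features$label, levels = c("normal", "scar"))
  if (anyNA(y)) {
    rs_stop("radonscar_bad_label", "labels must be 'scar' or 'normal'")
  }
  folds <- stratified_kfold(as.character(y), k = k, seed = seed)
  reports <- list()
  for (model in models) {
    per_fold <- vector("list", length(folds))
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_along(y), test_idx)
      if (length(unique(y[train_idx])) < 2L) {
        rs_stop("radonscar_degenerate_fold",
                "training fold %d contains a single class", f)
      }
      pred <- fit_and_predict(model, x[train_idx, , drop = FALSE], y[train_idx],
                              x[test_idx, , drop = FALSE], hy)
      truth <- as.character(y[test_idx])
      per_fold[[f]] <- list(
        tp = sum(pred == "scar" & truth == "scar"),
        fp = sum(pred == "scar" & truth == "normal"),
        tn = sum(pred == "normal" & truth == "normal"),
        fn = sum(pred == "normal" & truth == "scar")
      )
    }
    pooled <- list(
      tp = sum(vapply(per_fold, `[[`, 0L, "tp")),
      fp = sum(vapply(per_fold, `[[`, 0L, "fp")),
      tn = sum(vapply(per_fold, `[[`, 0L, "tn")),
      fn = sum(vapply(per_fold, `[[`, 0L, "fn"))
    )
    reports[[model]] <- c(
      list(model = model), confusion_metrics(pooled),
      list(folds = length(folds), seed = seed, counts = pooled,
           per_fold = per_fold)
    )
  }
  reports
}
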