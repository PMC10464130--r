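test_that("stratified folds partition the indices with balanced classes", {
  labels <- rep(c("scar", "normal"), each = 5)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(labels[f], c("scar", "normal"))
  }
  expect_setequal(unlist(folds), 1:10)

  set.seed(28)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    labels <- sample(c("scar", "normal"), n, replace = TRUE, prob = c(0.6, 0.4))
    k <- sample(2:5, 1)
    if (min(table(labels)) < k) next
    folds <- stratified_kfold(labels, k, seed = i)
    expect_setequal(unlist(folds), seq_len(n))
    expect_equal(sum(lengths(folds)), n)  # disjoint partition
    for (cls in c("scar", "normal")) {
      per_fold <- vapply(folds, function(f) sum(labels[f] == cls), 0)
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }

  expect_error(stratified_kfold(c("scar", rep("normal", 9)), k = 2, seed = 1),
               class = "radonscar_class_too_small")
})

test_that("confusion metrics implement the three standard ratios", {
  m <- confusion_metrics(list(tp = 50, fn = 0, tn = 50, fp = 0))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))

  m2 <- confusion_metrics(list(tp = 49, fn = 1, tn = 48, fp = 2))
  expect_equal(m2$sensitivity, 0.98)
  expect_equal(m2$specificity, 0.96)
  expect_equal(m2$accuracy, 0.97)

  set.seed(29)
  for (i in 1:20) {
    cnt <- as.list(stats::setNames(sample(1:50, 4, replace = TRUE),
                                   c("tp", "fp", "tn", "fn")))
    m3 <- confusion_metrics(cnt)
    expect_equal(m3$sensitivity, cnt$tp / (cnt$tp + cnt$fn))
    expect_equal(m3$specificity, cnt$tn / (cnt$tn + cnt$fp))
    expect_equal(m3$accuracy, (cnt$tp + cnt$tn) / sum(unlist(cnt)))
  }

  expect_error(confusion_metrics(list(tp = 0, fn = 0, tn = 5, fp = 5)),
               class = "radonscar_undefined_metric")
})

# a small but clearly separable phantom feature set, shared across blocks
separable_features <- function(seed, n_per_class = 40) {
  ps <- phantom_patch_sets(phantom_spec(seed = seed), n_per_class)
  patch_features(ps$patches)
}

test_that("cross-validated models recover the phantom's class structure", {
  feats <- separable_features(seed = 31)
  reports <- run_models(feats, k = 5, seed = 31)
  expect_named(reports, c("decision_tree", "svm", "logistic_regression"))
  expect_gte(reports$decision_tree$accuracy, 0.95)
  for (r in reports) {
    pooled <- r$counts
    expect_equal(pooled$tp + pooled$fp + pooled$tn + pooled$fn, nrow(feats))
    # pooled metrics are recomputable from the per-fold counts
    agg <- Reduce(function(a, b) Map(`+`, a, b), r$per_fold)
    expect_identical(pooled, agg)
    expect_equal(confusion_metrics(pooled)$accuracy, r$accuracy)
    # every sample is predicted exactly once across folds
    expect_equal(sum(unlist(pooled)), nrow(feats))
  }
})

test_that("identical class distributions give chance-level accuracy", {
  feats <- null_feature_set(n_per_class = 50, seed = 32)
  reports <- run_models(feats, k = 5, seed = 32)
  for (r in reports) {
    expect_gte(r$accuracy, 0.35)
    expect_lte(r$accuracy, 0.65)
  }
})

test_that("run_models is deterministic in the seed", {
  feats <- separable_features(seed = 33, n_per_class = 20)
  a <- run_models(feats, k = 5, seed = 9)
  b <- run_models(feats, k = 5, seed = 9)
  expect_identical(a, b)
})

test_that("permuting labels destroys above-chance accuracy", {
  feats <- separable_features(seed = 34, n_per_class = 30)
  accs <- numeric(20)
  for (i in 1:20) {
    shuffled <- feats
    shuffled$label <- radonscar:::with_seed(100 + i, sample(feats$label))
    accs[i] <- run_models(shuffled, k = 5, seed = i,
                          models = "decision_tree")$decision_tree$accuracy
  }
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})
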