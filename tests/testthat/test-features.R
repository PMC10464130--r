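test_that("lbp_code follows the >=-sets-the-bit convention", {
  expect_equal(lbp_code(5, rep(5, 8)), 255)
  expect_equal(lbp_code(5, rep(4.999, 8)), 0)
  expect_error(lbp_code(1, rep(1, 7)), class = "radonscar_bad_neighbors")

  set.seed(23)
  for (i in 1:1000) {
    ctr <- stats::runif(1)
    nb <- stats::runif(8)
    if (i %% 5 == 0) nb[sample(8, 2)] <- ctr  # exercise ties
    expect_identical(lbp_code(ctr, nb), oracle_lbp_code(ctr, nb))
  }
})

test_that("riu2 labels match the transition-count oracle on all 256 codes", {
  expect_equal(riu2_label(0), 0)
  expect_equal(riu2_label(255), 8)
  expect_equal(riu2_label(0x05), 9)  # two isolated bits, 4 transitions

  labels <- riu2_label(0:255)
  expect_identical(labels, vapply(0:255, oracle_riu2, 0L))
  expect_equal(sum(labels != 9), 58)  # exactly 58 uniform codes
  expect_error(riu2_label(256), class = "radonscar_bad_code")
})

test_that("riu2 labels are invariant to circular bit rotation", {
  rot8 <- function(code, s) {
    bitwAnd(bitwOr(bitwShiftL(code, s), bitwShiftR(code, 8 - s)), 255L)
  }
  for (code in 0:255) {
    for (s in 1:7) {
      expect_identical(riu2_label(rot8(code, s)), riu2_label(code))
    }
  }
})

test_that("lbp_feature histograms interior codes and normalizes", {
  f <- lbp_feature(matrix(3.7, 9, 9))
  expect_equal(unname(f), c(rep(0, 8), 1, 0))  # constant image codes to 255

  set.seed(24)
  for (i in 1:5) {
    img <- random_image(10)
    f <- lbp_feature(img)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
    expect_equal(unname(f), oracle_lbp_feature(img))
  }
  expect_error(lbp_feature(matrix(1, 2, 5)), class = "radonscar_image_too_small")
})

test_that("lbp_feature is invariant to strictly increasing intensity transforms", {
  set.seed(25)
  for (i in 1:5) {
    img <- random_image(12, lo = 0, hu = 50)
    f <- lbp_feature(img)
    expect_equal(lbp_feature(2 * img + 7), f)
    expect_equal(lbp_feature(img^3), f)
  }
})

test_that("class mean histograms average per-bin over one class", {
  fmat <- rbind(c(1, rep(0, 9)), c(0, 1, rep(0, 8)), rep(0.1, 10))
  colnames(fmat) <- paste0("f", 0:9)
  feats <- cbind(data.frame(patch_id = c("a", "b", "c"),
                            label = c("scar", "scar", "normal")),
                 as.data.frame(fmat))
  expect_equal(unname(class_mean_histogram(feats, "normal")), rep(0.1, 10))
  expect_equal(unname(class_mean_histogram(feats, "scar")),
               c(0.5, 0.5, rep(0, 8)))
  expect_error(class_mean_histogram(feats[feats$label == "scar", ], "normal"),
               class = "radonscar_no_features")

  set.seed(26)
  hmat <- t(replicate(6, random_histogram()))
  colnames(hmat) <- paste0("f", 0:9)
  feats2 <- cbind(data.frame(patch_id = letters[1:6],
                             label = rep(c("scar", "normal"), 3)),
                  as.data.frame(hmat))
  loop <- colSums(hmat[c(1, 3, 5), ]) / 3
  expect_equal(class_mean_histogram(feats2, "scar"), loop, tolerance = 1e-12)
})

test_that("wasserstein_1d equals the CDF formula and the quantile coupling", {
  p <- random_histogram()
  expect_equal(wasserstein_1d(p, p), 0)

  one_hot <- function(i) { h <- rep(0, 10); h[i] <- 1; h }
  expect_equal(wasserstein_1d(one_hot(1), one_hot(10)), 9)

  set.seed(27)
  for (i in 1:50) {
    a <- random_histogram(); b <- random_histogram(); cc <- random_histogram()
    d <- wasserstein_1d(a, b)
    expect_equal(d, oracle_wasserstein(a, b), tolerance = 1e-9)
    expect_equal(d, wasserstein_1d(b, a))
    expect_gte(d, 0)
    expect_lte(d, 9)
    expect_lte(d, wasserstein_1d(a, cc) + wasserstein_1d(cc, b) + 1e-12)
  }
  expect_error(wasserstein_1d(rep(0.2, 10), rep(0.1, 10)),
               class = "radonscar_bad_histogram")
})
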