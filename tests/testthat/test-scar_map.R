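test_that("region_stats computes mean and population SD over the mask", {
  img <- matrix(59, 4, 4)
  s <- region_stats(img, matrix(TRUE, 4, 4))
  expect_equal(s$mean, 59)
  expect_equal(s$sd, 0)
  expect_equal(s$n_pixels, 16)

  img2 <- matrix(c(0, 10, 99, 99), 2, 2)
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  s2 <- region_stats(img2, mask2)
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, 5)  # population SD of {0, 10}

  set.seed(8)
  img3 <- random_image(32); mask3 <- random_mask(32)
  s3 <- region_stats(img3, mask3)
  o <- oracle_region_stats(img3, mask3)
  expect_equal(s3$mean, o$mean, tolerance = 1e-9)
  expect_equal(s3$sd, o$sd, tolerance = 1e-9)
  expect_equal(s3$n_pixels, o$n)

  expect_error(region_stats(img3, matrix(FALSE, 32, 32)),
               class = "radonscar_empty_mask")
})

test_that("region growing floods the 4-connected tolerance component of the seed", {
  set.seed(9)
  distinct <- matrix(sample(1:64) * 100, 8, 8)
  only_seed <- region_grow(distinct, c(3, 5), tolerance = 0)
  expect_equal(sum(only_seed), 1)
  expect_true(only_seed[3, 5])

  expect_true(all(region_grow(distinct, c(1, 1), tolerance = Inf)))

  for (i in 1:5) {
    img <- matrix(sample(1:40, 256, replace = TRUE), 16, 16)
    seed <- c(sample(16, 1), sample(16, 1))
    got <- region_grow(img, seed, tolerance = 10)
    expect_identical(got, oracle_region_grow(img, seed, 10))
    expect_true(got[seed[1], seed[2]])
  }

  expect_error(region_grow(distinct, c(0, 3), 5), class = "radonscar_bad_seed")
})

test_that("scar_threshold admits exactly the pixels above mean + k*SD", {
  healthy <- list(mean = 59, sd = 21)
  myo <- matrix(TRUE, 2, 2)
  img <- matrix(c(123, 122.001, 122.000001, 123.5), 2, 2)
  got <- scar_threshold(img, myo, healthy, k = 3)  # cutoff 122, strict >
  expect_identical(as.vector(got), c(TRUE, TRUE, TRUE, TRUE))
  expect_false(any(scar_threshold(matrix(59, 3, 3), matrix(TRUE, 3, 3),
                                  healthy, k = 3)))
  expect_false(any(scar_threshold(matrix(122, 3, 3), matrix(TRUE, 3, 3),
                                  healthy, k = 3)))

  set.seed(10)
  img2 <- random_image(20, lo = 0, hu = 200)
  myo2 <- random_mask(20, p = 0.8)
  got2 <- scar_threshold(img2, myo2, healthy, k = 3)
  loop <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (cc in 1:20) {
    loop[r, cc] <- myo2[r, cc] && img2[r, cc] > 59 + 3 * 21
  }
  expect_identical(got2, loop)
  expect_true(all(got2 <= myo2))
  # raising k never adds pixels
  for (k in c(0, 1, 2, 2.5)) {
    expect_true(all(scar_threshold(img2, myo2, healthy, k = k + 0.5) <=
                    scar_threshold(img2, myo2, healthy, k = k)))
  }
})

test_that("the contrast rule is the mean + 2*SD threshold", {
  stats59 <- list(mean = 59, sd = 21)
  myo <- matrix(TRUE, 1, 2)
  img <- matrix(c(101, 101.5), 1, 2)  # cutoff 101
  expect_identical(as.vector(contrast_rule(img, myo, stats59)), c(FALSE, TRUE))

  zero_sd <- list(mean = 50, sd = 0)
  img2 <- matrix(c(49, 50, 51), 1, 3)
  expect_identical(as.vector(contrast_rule(img2, matrix(TRUE, 1, 3), zero_sd)),
                   c(FALSE, FALSE, TRUE))

  set.seed(11)
  img3 <- random_image(15); myo3 <- random_mask(15)
  expect_identical(contrast_rule(img3, myo3, stats59),
                   scar_threshold(img3, myo3, stats59, k = 2))
})

test_that("binarize_mean marks strictly-above-mean pixels inside the mask", {
  expect_false(any(binarize_mean(matrix(7, 5, 5), matrix(TRUE, 5, 5))))

  img <- matrix(c(0, 0, 0, 100), 2, 2)
  got <- binarize_mean(img, matrix(TRUE, 2, 2))  # mean 25
  expect_identical(got, img == 100)

  set.seed(12)
  img2 <- random_image(18); mask2 <- random_mask(18, p = 0.7)
  got2 <- binarize_mean(img2, mask2)
  mu <- mean(img2[mask2])
  loop <- matrix(FALSE, 18, 18)
  for (r in 1:18) for (cc in 1:18) {
    loop[r, cc] <- mask2[r, cc] && img2[r, cc] > mu
  }
  expect_identical(got2, loop)
})

test_that("scar_pipeline localizes phantom scar and removes speckle", {
  # no scar arcs -> nothing to find
  ph0 <- generate_phantom(phantom_spec(scar_arcs = list(), seed = 2))
  hs0 <- region_stats(ph0$image, ph0$myocardium)
  expect_false(any(scar_pipeline(ph0$image, ph0$myocardium,
                                 list(mean = hs0$mean, sd = hs0$sd))))

  # default phantom: high overlap with ground truth
  ph <- generate_phantom(phantom_spec(seed = 3))
  hs <- estimate_healthy_stats(ph$image, ph$myocardium)
  final <- scar_pipeline(ph$image, ph$myocardium, hs)
  expect_gte(dice_coefficient(final, ph$scar), 0.8)
  expect_true(all(final <= ph$myocardium))

  # isolated single-pixel noise is erased by opening with the 3x3 square
  img <- matrix(50, 30, 30)
  img[15, 15] <- 500
  got <- scar_pipeline(img, matrix(TRUE, 30, 30), list(mean = 50, sd = 10))
  expect_false(any(got))
})
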