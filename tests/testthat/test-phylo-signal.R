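test_that("a two-tip contrast matches the hand recursion", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cs <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(nrow(cs), 1)
  expect_equal(abs(cs$contrast), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(cs$expected_sd, sqrt(2), tolerance = 1e-12)
})

test_that("contrasts of a constant trait are zero and count n_tips - 1", {
  tr <- random_unit_tree(12, seed = 3)
  cs <- pic_contrasts(tr, stats::setNames(rep(2.5, 12), tr$tip.label))
  expect_equal(nrow(cs), 11)
  expect_equal(cs$contrast, rep(0, 11))
  expect_error(pic_contrasts(tr, c(sp01 = 1)), "trait value")
})

test_that("through-origin contrast regression equals the GLS slope", {
  for (seed in 1:6) {
    tr <- random_unit_tree(6, seed = seed)
    x <- bm_trait(tr); y <- 0.6 * x + bm_trait(tr)
    cx <- pic_contrasts(tr, x)$contrast
    cy <- pic_contrasts(tr, y)$contrast
    slope_pic <- sum(cx * cy) / sum(cx^2)
    expect_equal(slope_pic, gls_slope(tr, x, y), tolerance = 1e-8)
  }
})

test_that("low-variance filtering applies the expected-SD threshold", {
  cs <- structure(data.frame(node = 1:9, contrast = rnorm(9),
                             expected_sd = c(0.05, 0.1, 0.2, 0.3, 0.5,
                                             0.7, 1, 1.5, 2)),
                  class = c("contrast_set", "data.frame"))
  kept <- filter_low_variance_contrasts(cs, threshold = 0.21)
  expect_equal(nrow(kept), 6)
  expect_equal(attr(kept, "n_removed"), 3)
  expect_equal(nrow(filter_low_variance_contrasts(cs, 0)), 9)
  expect_equal(nrow(filter_low_variance_contrasts(cs, Inf)), 0)
})

test_that("lambda is recovered near 1 under BM and near 0 for shuffled traits", {
  tr <- random_unit_tree(100, seed = 1)
  lams <- shuf <- numeric(50)
  set.seed(99)
  for (i in 1:50) {
    x <- bm_trait(tr)
    lams[i] <- pagel_lambda(tr, x)$lambda
    shuf[i] <- pagel_lambda(tr, stats::setNames(sample(x), names(x)))$lambda
  }
  expect_gte(mean(lams), 0.9)
  expect_lte(mean(lams), 1.0)
  expect_lt(stats::median(shuf), 0.1)
  expect_true(all(lams >= 0 & lams <= 1))
})

test_that("lambda agrees with the reference ML implementation", {
  skip_if_not_installed("phytools")
  tr <- random_unit_tree(40, seed = 7)
  set.seed(3)
  x <- bm_trait(tr) + rnorm(40, 0, 0.3)  # intermediate signal
  mine <- pagel_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  if (ref$lambda <= 1) {
    expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
    expect_equal(mine$logL, ref$logL, tolerance = 1e-4)
  } else {
    expect_equal(mine$lambda, 1)  # box-constrained at the boundary
  }
})

test_that("Blomberg's K is calibrated to 1 under BM and small for white noise", {
  tr <- random_unit_tree(60, seed = 5)
  set.seed(42)
  ks <- replicate(50, blomberg_k(tr, bm_trait(tr), n_perm = 0)$K)
  expect_gte(mean(ks), 0.8)
  expect_lte(mean(ks), 1.2)
  wn <- stats::setNames(rnorm(60), tr$tip.label)
  expect_lt(blomberg_k(tr, wn, n_perm = 0)$K, 0.5)
  # permutation p: strong signal detected, and n_perm = 0 gives NA
  res <- blomberg_k(tr, bm_trait(tr), n_perm = 199, seed = 1)
  expect_lt(res$p, 0.05)
  expect_true(is.na(blomberg_k(tr, wn, n_perm = 0)$p))
})

test_that("K matches the reference implementation", {
  skip_if_not_installed("phytools")
  tr <- random_unit_tree(30, seed = 11)
  set.seed(8)
  x <- bm_trait(tr)
  expect_equal(blomberg_k(tr, x, n_perm = 0)$K,
               unclass(phytools::phylosig(tr, x, method = "K"))[[1]],
               tolerance = 1e-8)
})

test_that("lambda and K are invariant to affine trait transformation", {
  tr <- random_unit_tree(40, seed = 13)
  set.seed(5)
  x <- bm_trait(tr) + rnorm(40, 0, 0.2)
  l1 <- pagel_lambda(tr, x)$lambda
  l2 <- pagel_lambda(tr, 3 * x - 7)$lambda
  expect_equal(l1, l2, tolerance = 1e-4)
  expect_equal(blomberg_k(tr, x, 0)$K, blomberg_k(tr, 3 * x - 7, 0)$K,
               tolerance = 1e-10)
})

test_that("standardized contrasts are iid normal under BM", {
  pooled <- numeric(0)
  for (seed in 1:21) {
    tr <- random_unit_tree(50, seed = 100 + seed)
    set.seed(200 + seed)
    pooled <- c(pooled, pic_contrasts(tr, bm_trait(tr))$contrast)
  }
  pooled <- pooled[1:1000]
  expect_gt(stats::shapiro.test(pooled)$p.value, 0.01)
})

test_that("sister pairs are disjoint mixed-label cherries", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  labs <- c(A = "obligate", B = "opportunistic", C = "obligate", D = "opportunistic")
  prs <- sister_pairs(tr, labs)
  expect_equal(nrow(prs), 2)
  expect_equal(anyDuplicated(c(prs$tip1, prs$tip2)), 0)
  same <- c(A = "x", B = "x", C = "y", D = "y")
  expect_warning(none <- sister_pairs(tr, same), "no mixed-label")
  expect_equal(nrow(none), 0)
  expect_error(sister_pairs(tr, labs[-1]), "label")
})
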