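test_that("Pearson correlation matches hand computation and invariances", {
  expect_equal(pearson(1:4, 2 * (1:4) + 1)$r, 1)
  r <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r, 0.6)
  expect_equal(r$n, 4)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson(x, y)$r, pearson(y, x)$r)
  expect_equal(pearson(3 * x + 2, y)$r, pearson(x, y)$r)
  expect_error(pearson(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson(1:2, 1:2), "3 complete pairs")
})

test_that("through-origin correlation uses n - 1 degrees of freedom", {
  x <- c(1, -2, 3, -1, 2); y <- 0.5 * x + c(0.1, -0.2, 0.1, 0, -0.1)
  r <- pearson(x, y, through_origin = TRUE)
  r_manual <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(r$r, r_manual)
  tt <- r_manual * sqrt((5 - 1) / (1 - r_manual^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 4))
})

test_that("common-slope ANCOVA recovers exact and noisy slopes", {
  d <- data.frame(x = rep(1:4, 2), g = rep(c("a", "b"), each = 4))
  d$y <- 3 * d$x + ifelse(d$g == "a", 1, 5)
  # exact fit: silence lm's perfect-fit warning, the determinism is the point
  fit <- suppressWarnings(ancova_common_slope(d, y = "y", x = "x", group = "g"))
  expect_equal(fit$common_slope, 3, tolerance = 1e-12)
  expect_lt(fit$p, 1e-10)
  expect_equal(unname(fit$group_intercepts), c(1, 5), tolerance = 1e-10)
  # singleton groups are dropped with a warning
  set.seed(2)
  d1 <- data.frame(x = rnorm(9), g = rep(c("a", "b", "c"), c(4, 4, 1)))
  d1$y <- d1$x + rnorm(9, 0, 0.2)
  expect_warning(fit1 <- ancova_common_slope(d1, "y", "x", "g"), "single point")
  expect_equal(fit1$n_groups, 2)
  # matches the direct normal-equations solution
  set.seed(1)
  d2 <- data.frame(x = rnorm(12), g = rep(c("a", "b", "c"), each = 4))
  d2$y <- 0.7 * d2$x + rep(c(0, 1, -1), each = 4) + rnorm(12, 0, 0.1)
  fit2 <- ancova_common_slope(d2, "y", "x", "g")
  X <- cbind(model.matrix(~ factor(d2$g) - 1), d2$x)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(fit2$common_slope, as.numeric(beta[4, 1]), tolerance = 1e-10)
})

test_that("standardized regression reduces to Pearson r for one predictor", {
  set.seed(7)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  fit <- multiple_regression_standardized(data.frame(x = x), y)
  expect_equal(unname(fit$coefficients), pearson(x, y)$r, tolerance = 1e-10)
  # null coefficients are near zero
  X <- data.frame(a = rnorm(200), b = rnorm(200))
  fit0 <- multiple_regression_standardized(X, rnorm(200))
  expect_true(all(abs(fit0$coefficients) < 0.2))
  # duplicated predictor triggers a rank error naming the column
  expect_error(multiple_regression_standardized(data.frame(a = x, b = x), y),
               "collinear.*b")
  expect_error(multiple_regression_standardized(data.frame(a = rep(1, 30)), y),
               "constant")
})

test_that("detectable correlation follows the Fisher-z closed form", {
  expect_equal(detectable_correlation(34, 0.05, 0.95), 0.56995, tolerance = 1e-4)
  expect_lt(detectable_correlation(10000), 0.05)
  ns <- c(10, 20, 50, 200, 1000)
  expect_true(all(diff(detectable_correlation(ns)) < 0))
})

test_that("t-tests handle degenerate, paired and unpaired cases", {
  same <- group_ttest(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3), paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(group_ttest(1:4, c("a", "a", "a", "b")), ">= 2 values")
  expect_error(group_ttest(1:6, rep("a", 6)), "two groups")
})

test_that("t-test p agrees with the exhaustive permutation distribution", {
  perm_p <- function(a, b) {
    vals <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    diffs <- apply(combn(6, 3), 2, function(ix)
      abs(mean(vals[ix]) - mean(vals[-ix])))
    mean(diffs >= obs - 1e-12)
  }
  a <- c(-1.4, -0.3, -0.1); b <- c(1.6, 0.7, -1.7)
  expect_equal(group_ttest(c(a, b), rep(c("a", "b"), each = 3))$p,
               perm_p(a, b), tolerance = 0.1)
  a2 <- c(-1.7, -0.4, -0.5); b2 <- c(3.7, -0.4, 1.1)
  expect_equal(group_ttest(c(a2, b2), rep(c("a", "b"), each = 3))$p,
               perm_p(a2, b2), tolerance = 0.1)
})

test_that("pearson and ANCOVA p-values are uniform under the null", {
  set.seed(31)
  p_cor <- replicate(500, pearson(rnorm(20), rnorm(20))$p)
  expect_gt(stats::ks.test(p_cor, "punif")$p.value, 0.01)
  p_anc <- replicate(500, {
    d <- data.frame(x = rnorm(20), g = rep(letters[1:5], each = 4),
                    y = rep(rnorm(5), each = 4) + rnorm(20))
    ancova_common_slope(d, "y", "x", "g")$p
  })
  expect_gt(stats::ks.test(p_anc, "punif")$p.value, 0.01)
})
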