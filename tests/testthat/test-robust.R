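test_that("pseudomedian matches Walsh-average enumeration on known cases", {
  expect_equal(hodges_lehmann(5), 5)
  expect_equal(hodges_lehmann(c(1, 2, 3)), 2)
  # Walsh averages of {1,2,6}: {1, 1.5, 2, 3.5, 4, 6} -> median 2.75
  expect_equal(hodges_lehmann(c(1, 2, 6)), 2.75)
  expect_error(hodges_lehmann(numeric()), "non-empty")
})

test_that("pseudomedian equals independent oracles on random samples", {
  withr::with_seed(99, {
    for (n in c(2, 3, 7, 20, 75, 200)) {
      x <- rlnorm(n, 3, 0.6)
      expect_equal(hodges_lehmann(x), hl_oracle(x))
      # wilcox.test's pseudomedian estimator as a second, independent route
      # wilcox.test locates the estimate numerically; agreement to ~1e-3
      wt <- suppressWarnings(stats::wilcox.test(x, conf.int = TRUE))
      expect_equal(hodges_lehmann(x), unname(wt$estimate), tolerance = 1e-3)
    }
  })
})

test_that("outlier filter removes only points beyond k raw SD of the pseudomedian", {
  f0 <- filter_outliers(c(7, 7, 7, 7))
  expect_length(f0$removed, 0)

  x <- c(9, 10, 10, 11, 10, 9, 11, 10, 10, 50)
  f <- filter_outliers(x, k = 3)
  expect_equal(f$removed, 50)
  expect_equal(sort(c(f$kept, f$removed)), sort(x))
  expect_equal(f$sd_used, sd(x))
  expect_true(all(f$kept >= f$lower_bound & f$kept <= f$upper_bound))

  expect_length(filter_outliers(x, k = 1e6)$removed, 0)
})

test_that("filtering is single-pass: bounds do not tighten on re-application", {
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- c(rnorm(50, 10, 2), rlnorm(3, 4, 1))
      f <- filter_outliers(x)
      again <- f$kept[abs(f$kept - f$pseudomedian) <= 3 * f$sd_used]
      expect_equal(again, f$kept)
      expect_true(all(sort(c(f$kept, f$removed)) == sort(x)))
    }
  })
})

test_that("short samples pass through the filter untouched", {
  expect_equal(filter_outliers(c(3))$kept, 3)
  expect_length(filter_outliers(numeric())$kept, 0)
})

test_that("bootstrap variance is reproducible and sane on degenerate input", {
  x <- rep(2.5, 30)
  bv <- bootstrap_variance(x, B = 100, seed = 1)
  expect_equal(bv$point_estimate, 0)
  expect_equal(bv$se_of_estimate, 0)

  withr::with_seed(11, y <- rnorm(80, 50, 6))
  b1 <- bootstrap_variance(y, B = 200, seed = 5)
  b2 <- bootstrap_variance(y, B = 200, seed = 5)
  expect_identical(b1$se_of_estimate, b2$se_of_estimate)
  b3 <- bootstrap_variance(y, B = 200, seed = 6)
  expect_false(identical(b1$se_of_estimate, b3$se_of_estimate))
})

test_that("bootstrap SE matches the analytic SE of a normal-sample variance", {
  withr::with_seed(2024, x <- rnorm(200, 100, 10))
  bv <- bootstrap_variance(x, B = 1000, seed = 3)
  analytic <- var(x) * sqrt(2 / (length(x) - 1))
  expect_equal(bv$se_of_estimate, analytic, tolerance = 0.25)
})

test_that("signed-rank test matches hand enumeration on the 3-point sample", {
  wt <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(wt$statistic, 6)
  expect_equal(wt$p_value, 0.25)
  expect_equal(wt$method, "exact")
})

test_that("signed-rank V is maximal-rank-sum bounded and null for symmetric data", {
  x <- c(-2, -1, 1, 2)
  wt <- wilcoxon_signed_rank(x)
  n <- wt$n_effective
  expect_equal(wt$statistic, n * (n + 1) / 4)
  expect_gte(wt$p_value, 0.99)
  zeroes <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(zeroes$all_zero)
  expect_equal(zeroes$p_value, 1)
  expect_equal(zeroes$statistic, 6 * 7 / 4)
})

test_that("exact signed-rank p equals 2^n enumeration on random samples", {
  withr::with_seed(7, {
    for (i in 1:12) {
      n <- sample(4:12, 1)
      x <- round(rnorm(n, 0.3, 1), 1)  # rounding induces ties and zeros
      got <- wilcoxon_signed_rank(x)
      expect_equal(got$p_value, wilcoxon_oracle_p(x), tolerance = 1e-12)
      expect_gte(got$p_value, 0)
      expect_lte(got$p_value, 1)
    }
  })
})

test_that("exact and tie-free R implementations agree without ties", {
  withr::with_seed(8, {
    for (i in 1:8) {
      x <- rnorm(10, 0.5)
      got <- wilcoxon_signed_rank(x)
      ref <- stats::wilcox.test(x, exact = TRUE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(9, x <- rnorm(60, 0.2))
  got <- wilcoxon_signed_rank(x)
  expect_equal(got$method, "normal-approximation")
  ref <- stats::wilcox.test(x, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("slope z-test has the closed form and its symmetries", {
  expect_equal(slope_z_test(1, 0.5, 1, 0.7)$z, 0)
  expect_equal(slope_z_test(1, 0.5, 1, 0.7)$p_value, 1)
  zt <- slope_z_test(1, 0.1, 0, 0.1)
  expect_equal(zt$z, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(zt$z, 7.071, tolerance = 1e-3)
  a <- slope_z_test(0.4, 0.1, -0.2, 0.3)
  b <- slope_z_test(-0.2, 0.3, 0.4, 0.1)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  # reduces to b/se against zero
  expect_equal(slope_z_test(-0.3, 0.01)$z, -30)
  expect_error(slope_z_test(1, 0, 2, 0), "positive")
})

test_that("Bonferroni adjustment multiplies by family size with a cap", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.06, 1))
  withr::with_seed(3, p <- runif(15))
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
})

test_that("block-trend regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(2.1, 2.4, 3.9, 4.2, 7.3)
  bt <- block_trend_regression(x, y)
  # hand solution of the normal equations
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- mean(y) - b_hat * mean(x)
  expect_equal(bt$slope, b_hat)
  expect_equal(bt$intercept, a_hat)
  s2 <- sum((y - a_hat - b_hat * x)^2) / (length(x) - 2)
  expect_equal(bt$slope_se, sqrt(s2 / sum((x - mean(x))^2)))
  expect_equal(bt$df, 3L)

  flat <- block_trend_regression(1:5, rep(2, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$t, 0)

  perfect <- block_trend_regression(1:5, 2 * (1:5) + 1)
  expect_equal(perfect$slope, 2)
  expect_true(perfect$perfect_fit)
  expect_identical(perfect$t, Inf)

  expect_error(block_trend_regression(rep(3, 5), rnorm(5)), "all equal")
})
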