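test_that("a noiseless line is recovered exactly with zero chi-square", {
  x <- seq(10, 130, by = 10)
  y <- 4.2 - 0.25 * x
  f <- fit_line(x, y, se = rep(0.5, length(x)))
  expect_equal(f$slope, -0.25)
  expect_equal(f$intercept, 4.2)
  expect_equal(f$chisq, 0)
  expect_equal(f$df, length(x) - 2L)
})

test_that("weighted fit matches the closed-form normal equations", {
  x <- c(1, 4, 9)
  y <- c(2.0, 3.5, 8.1)
  se <- c(0.2, 0.5, 1.0)
  w <- 1 / se^2
  # hand-solved 2x2 weighted normal equations
  S <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x^2)
  Sy <- sum(w * y); Sxy <- sum(w * x * y)
  det <- S * Sxx - Sx^2
  a_hat <- (Sxx * Sy - Sx * Sxy) / det
  b_hat <- (S * Sxy - Sx * Sy) / det
  f <- fit_line(x, y, se = se)
  expect_equal(f$slope, b_hat)
  expect_equal(f$intercept, a_hat)
  expect_equal(f$slope_se, sqrt(S / det))
  expect_equal(f$intercept_se, sqrt(Sxx / det))
  expect_equal(f$chisq, sum(w * (y - a_hat - b_hat * x)^2))
  # coefficients agree with lm(weights = 1/se^2) as an independent route
  lmfit <- stats::lm(y ~ x, weights = w)
  expect_equal(unname(stats::coef(lmfit)), c(a_hat, b_hat))
})

test_that("through-origin weighted slope is sum(wxy)/sum(wx2)", {
  x <- c(2, 5, 11)
  y <- c(0.5, 0.9, 2.4)
  se <- c(0.1, 0.15, 0.3)
  w <- 1 / se^2
  f <- fit_line(x, y, se = se, intercept = FALSE)
  expect_equal(f$slope, sum(w * x * y) / sum(w * x^2))
  expect_equal(f$slope_se, 1 / sqrt(sum(w * x^2)))
  expect_true(is.na(f$intercept))
})

test_that("zero-SE points get the minimum positive SE instead of infinite weight", {
  x <- 1:5
  y <- c(1, 2.1, 2.9, 4.2, 5)
  se <- c(0.2, 0, 0.2, 0.2, 0.2)
  f <- fit_line(x, y, se = se)
  ref <- fit_line(x, y, se = rep(0.2, 5))
  expect_equal(f$slope, ref$slope)
  expect_error(fit_line(x, y, se = rep(0, 5)), "zero or missing")
})

test_that("RMSE proportional to the estimate yields cv equal to the ratio", {
  bins <- tibble::tibble(
    condition = "sitting", task = "look", nominal_s = 60,
    bin_start = 1:6, bin_center = c(20, 40, 60, 80, 100, 120),
    n = 30, mean_bias = 0, se_bias = 1,
    mean_estimate = c(20, 40, 60, 80, 100, 120)
  )
  bins$rmse <- 0.2 * bins$mean_estimate
  cv <- fit_rmse_line(bins, mode = "vs_estimate")
  expect_equal(cv$cv, 0.2)
  f <- fit_rmse_line(bins, mode = "vs_duration")
  expect_equal(f$slope, 0.2)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
})

test_that("reference-table mean biases reproduce the published solve slopes", {
  ref <- reference_cell_means()
  hard_sit <- ref[ref$condition == "sitting" & ref$task == "solve_hard", ]
  f <- fit_line(hard_sit$nominal_s, hard_sit$mean_estimate - hard_sit$nominal_s)
  expect_equal(f$slope, -0.3, tolerance = 0.05 / 0.3)
  expect_equal(round(f$slope, 2), -0.29)
})

test_that("end-to-end fits recover generator parameters within 2 SE (typical seed)", {
  d <- generate_design(design_spec(rng_seed = 11))
  tr <- linear_clock_model(d, seed = 12)
  bins <- suppressMessages(make_bins(compute_bias(tr)))
  f <- fit_bias_line(bins)
  cp <- default_clock_params()
  m <- merge(as.data.frame(f), as.data.frame(cp), by = c("condition", "task"))
  zs <- abs(m$slope - (m$gain - 1)) / m$slope_se
  zi <- abs(m$intercept - m$offset) / m$intercept_se
  # a single cohort: most cells within 2 SE, none grossly off
  expect_gte(sum(zs <= 2 & zi <= 2), 6)
  expect_true(all(zs <= 3 & zi <= 3))
  # fitted RMSE-vs-duration slope tracks cv * gain
  rf <- fit_rmse_line(bins, mode = "vs_duration")
  m2 <- merge(as.data.frame(rf), as.data.frame(cp), by = c("condition", "task"))
  expect_equal(m2$slope, m2$cv * m2$gain, tolerance = 0.35)
})

test_that("pacemaker cohorts yield bias lines with near-zero intercept and gate-ratio slope", {
  d <- generate_design(design_spec(rng_seed = 19))
  tr <- pacemaker_accumulator_model(d, seed = 20)
  bins <- suppressMessages(make_bins(compute_bias(tr)))
  f <- fit_bias_line(bins)
  pp <- default_pacemaker_params()
  m <- merge(as.data.frame(f), as.data.frame(pp), by = c("condition", "task"))
  slope_true <- m$gate_prob / m$ref_gate - 1
  expect_true(all(abs(m$slope - slope_true) <= 3 * m$slope_se))
  expect_true(all(abs(m$intercept) <= 3 * m$intercept_se))
})

test_that("chi-square is calibrated when per-bin noise matches the stated SEs", {
  withr::with_seed(77, {
    x <- seq(14, 130, length.out = 37)
    se <- rep(1.2, 37)
    chis <- replicate(150, {
      y <- 5 - 0.2 * x + rnorm(37, 0, se)
      fit_line(x, y, se = se)$chisq
    })
    expect_equal(mean(chis), 35, tolerance = 0.06)
  })
})

test_that("pairwise slope comparisons are antisymmetric and complete", {
  fits <- tibble::tibble(condition = "sitting",
                         task = c("a", "b", "c"),
                         slope = c(0.1, -0.2, 0.05),
                         slope_se = c(0.05, 0.05, 0.02))
  cmp <- compare_slopes(fits)
  expect_equal(nrow(cmp), 3)
  z12 <- slope_z_test(0.1, 0.05, -0.2, 0.05)$z
  expect_equal(cmp$z[cmp$cell_1 == "sitting/a" & cmp$cell_2 == "sitting/b"], z12)
})

test_that("CV estimation offers fit and whole-process bootstrap SEs", {
  tr <- small_cohort(n_participants = 6, seed = 71)
  b <- compute_bias(tr)
  fit_route <- estimate_cv(b)
  expect_equal(fit_route$cv,
               fit_rmse_line(suppressMessages(make_bins(b)),
                             mode = "vs_estimate")$cv)
  boot1 <- estimate_cv(b, se_method = "bootstrap", B = 50, seed = 3)
  boot2 <- estimate_cv(b, se_method = "bootstrap", B = 50, seed = 3)
  expect_equal(boot1$cv_se, boot2$cv_se)
  expect_equal(boot1$cv, fit_route$cv)  # point estimate unchanged
  # bootstrap SEs include filter-bound randomness: at least as large on average
  expect_gt(mean(boot1$cv_se), 0.8 * mean(fit_route$cv_se))
})
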