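test_that("identity clock reproduces true durations exactly", {
  d <- generate_design(small_spec())
  tr <- linear_clock_model(d, identity_params(), seed = 1)
  expect_equal(tr$estimate_s, tr$actual_s)
})

test_that("noiseless clock applies offset and gain deterministically", {
  d <- generate_design(small_spec(n_participants = 1, conditions = "sitting"))
  cp <- default_clock_params(cv = 0, outlier_rate = 0)
  tr <- linear_clock_model(d, cp, seed = 1)
  look <- tr[tr$task == "look", ]
  expect_equal(look$estimate_s, 6.4 + 1.005 * look$actual_s)
  # a 100-s trial under the look/sitting cell would read 106.9
  expect_equal(6.4 + 1.005 * 100, 106.9)
})

test_that("linear clock noise matches the configured coefficient of variation", {
  d <- tibble::tibble(condition = "sitting", task = "look",
                      nominal_s = 60, actual_s = 60)
  d <- d[rep(1, 1e4), ]
  cp <- clock_params("sitting", "look", offset = 0, gain = 1,
                     cv = 0.2, outlier_rate = 0)
  tr <- linear_clock_model(d, cp, seed = 21)
  expect_equal(sd(tr$estimate_s) / mean(tr$estimate_s), 0.2, tolerance = 0.05)
  # log-normal mode keeps the same mean and CV
  trl <- linear_clock_model(d, cp, seed = 22, noise = "lognormal")
  expect_equal(mean(trl$estimate_s), 60, tolerance = 0.01)
  expect_equal(sd(trl$estimate_s) / mean(trl$estimate_s), 0.2,
               tolerance = 0.05)
  # and is right-skewed, unlike the gaussian branch
  sk <- function(v) mean(((v - mean(v)) / sd(v))^3)
  expect_gt(sk(trl$estimate_s), 0.3)
})

test_that("contaminant trials inflate the tails at the configured rate", {
  d <- tibble::tibble(condition = "sitting", task = "look",
                      nominal_s = 60, actual_s = 60)[rep(1, 2e4), ]
  clean <- clock_params("sitting", "look", 0, 1, cv = 0.1, outlier_rate = 0)
  dirty <- clock_params("sitting", "look", 0, 1, cv = 0.1,
                        outlier_rate = 0.05, outlier_scale = 8)
  e_clean <- linear_clock_model(d, clean, seed = 5)$estimate_s
  e_dirty <- linear_clock_model(d, dirty, seed = 5)$estimate_s
  tail_rate <- function(e) mean(abs(e - 60) > 3 * 0.1 * 60)
  expect_lt(tail_rate(e_clean), 0.005)
  expect_gt(tail_rate(e_dirty), 0.02)
})

test_that("missing parameter cells are reported by name", {
  d <- generate_design(small_spec())
  cp <- default_clock_params()[-2, ]  # drop sitting/read
  expect_error(linear_clock_model(d, cp), "sitting / read")
})

test_that("calibrated pacemaker is veridical on average", {
  d <- tibble::tibble(condition = "sitting", task = "look",
                      nominal_s = 60, actual_s = 60)[rep(1, 1e4), ]
  pp <- pacemaker_params("sitting", "look", gate_prob = 1, base_rate = 1000,
                         ref_gate = 1, gain_noise_sd = 0)
  e <- pacemaker_accumulator_model(d, pp, seed = 3)$estimate_s
  expect_equal(mean(e), 60, tolerance = 0.1 / 60)
})

test_that("gate losses shrink pacemaker estimates proportionally", {
  d <- tibble::tibble(condition = "sitting", task = "look",
                      nominal_s = 90, actual_s = 100)[rep(1, 1e4), ]
  pp <- pacemaker_params("sitting", "look", gate_prob = 0.8, base_rate = 1000,
                         ref_gate = 1, gain_noise_sd = 0)
  e <- pacemaker_accumulator_model(d, pp, seed = 4)$estimate_s
  expect_equal(mean(e), 80, tolerance = 0.005)
})

test_that("rate noise gives the pacemaker the scalar property", {
  cvs <- sapply(c(30, 60, 120), function(dur) {
    d <- tibble::tibble(condition = "sitting", task = "look",
                        nominal_s = dur, actual_s = dur)[rep(1, 1e4), ]
    pp <- pacemaker_params("sitting", "look", gate_prob = 0.9,
                           base_rate = 200, ref_gate = 0.9,
                           gain_noise_sd = 0.2)
    e <- pacemaker_accumulator_model(d, pp, seed = dur)$estimate_s
    sd(e) / mean(e)
  })
  expect_equal(cvs, rep(0.2, 3), tolerance = 0.05)
})

test_that("zero reference gate is rejected", {
  expect_error(pacemaker_params("sitting", "look", 0.5, ref_gate = 0),
               "ref_gate")
})

test_that("both generators produce identical output for identical seeds", {
  d <- generate_design(small_spec())
  expect_identical(linear_clock_model(d, seed = 9),
                   linear_clock_model(d, seed = 9))
  expect_identical(pacemaker_accumulator_model(d, seed = 9),
                   pacemaker_accumulator_model(d, seed = 9))
  expect_false(identical(linear_clock_model(d, seed = 9),
                         linear_clock_model(d, seed = 10)))
})

test_that("estimate CV is constant across durations for the default generator", {
  d <- generate_design(design_spec(n_participants = 8, rng_seed = 31,
                                   conditions = "sitting"))
  tr <- linear_clock_model(d, default_clock_params(outlier_rate = 0),
                           seed = 32)
  look <- tr[tr$task == "look", ]
  cv_by_T <- sapply(split(look$estimate_s, look$nominal_s),
                    function(e) sd(e) / mean(e))
  expect_lt(max(cv_by_T) - min(cv_by_T), 0.08)
})

test_that("covariate generator reproduces configured block trends", {
  d <- generate_design(small_spec(n_participants = 8, rng_seed = 2))
  tr <- default_covariate_trends()
  cov <- generate_covariates(d, tr, seed = 6)
  expect_true(all(cov$fatigue >= 1 & cov$fatigue <= 7))
  expect_true(all(cov$fatigue == round(cov$fatigue)))
  expect_true(all(cov$temp_c >= 35 & cov$temp_c <= 39))
  walk <- cov[cov$condition == "walking", ]
  fit <- block_trend_regression(walk$block_in_session, walk$fatigue)
  expect_lt(abs(fit$slope - 0.15), 0.03)
  sit_t <- cov[cov$condition == "sitting", ]
  fit_t <- block_trend_regression(sit_t$block_in_session, sit_t$temp_c)
  expect_lt(abs(fit_t$slope), 0.02)
})

test_that("flat noiseless covariates round onto the Likert scale", {
  d <- generate_design(small_spec())
  tr <- default_covariate_trends()
  tr$slope <- 0
  tr$noise_sd <- 0
  tr$intercept[tr$variable == "fatigue"] <- 1.6
  cov <- generate_covariates(d, tr, seed = 1)
  expect_true(all(cov$fatigue == 2))  # 1.6 rounded to scale resolution
})

test_that("math performance recovers configured accuracy and RT means", {
  d <- generate_design(design_spec(n_participants = 12, rng_seed = 8))
  tr <- add_math_performance(d, seed = 13)
  expect_true(all(is.na(tr$correct[tr$task %in% c("look", "read")])))
  hard_walk <- tr[tr$task == "solve_hard" & tr$condition == "walking", ]
  expect_equal(mean(hard_walk$correct), 0.913, tolerance = 0.02)
  hard_sit <- tr[tr$task == "solve_hard" & tr$condition == "sitting", ]
  expect_equal(mean(hard_sit$rt_s), 3.02, tolerance = 0.06)
})
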