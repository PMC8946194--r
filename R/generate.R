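join_params <- function(design, params, needed_cols, what) {
  cells <- unique(design[, c("condition", "task")])
  have <- paste(params$condition, params$task)
  missing <- cells[!(paste(cells$condition, cells$task) %in% have), ]
  if (nrow(missing) > 0) {
    stop("No ", what, " for cell(s): ",
         paste(missing$condition, "/", missing$task, collapse = ", "),
         call. = FALSE)
  }
  dplyr::left_join(design, params[, c("condition", "task", needed_cols)],
                   by = c("condition", "task"))
}

#' Simulate verbal estimates with a linear internal-clock model
#'
#' For each trial with true duration `d`, the estimate is
#' `e = offset + gain * d + noise`, with zero-mean noise whose SD is
#' `cv * (offset + gain * d)` (constant coefficient of variation, the scalar
#' property). With probability `outlier_rate` the SD is inflated by
#' `outlier_scale`, providing the heavy right-and-left tails the outlier
#' filter is designed to remove. Estimates are floored at `floor_s` seconds.
#'
#' @param design Trial table from [generate_design()].
#' @param params A [clock_params()] table covering every (condition, task)
#'   cell present in `design`.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @param noise `"gaussian"` (default) or `"lognormal"`. Both have the same
#'   mean and CV; the log-normal option adds the right skew plausible for
#'   verbal magnitude reports.
#' @param floor_s Minimum reported estimate in seconds (default 1).
#' @return `design` with `estimate_s` filled in.
#' @export
#' @examples
#' d <- generate_design(design_spec(n_participants = 1, conditions = "sitting"))
#' trials <- linear_clock_model(d, seed = 7)
#' head(trials)
linear_clock_model <- function(design, params = default_clock_params(),
                               seed = 1L, noise = c("gaussian", "lognormal"),
                               floor_s = 1) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(design), all(c("condition", "task", "actual_s")
                                       %in% names(design)))
  df <- join_params(design, params,
                    c("offset", "gain", "cv", "outlier_rate", "outlier_scale"),
                    "clock parameters")
  withr::with_seed(seed, {
    mu <- df$offset + df$gain * df$actual_s
    sdev <- df$cv * pmax(mu, floor_s)
    contaminant <- runif(nrow(df)) < df$outlier_rate
    sdev[contaminant] <- sdev[contaminant] * df$outlier_scale[contaminant]
    e <- if (noise == "gaussian") {
      mu + rnorm(nrow(df)) * sdev
    } else {
      # match mean and SD of the gaussian branch on the original scale
      sigma <- sqrt(log1p((sdev / pmax(mu, floor_s))^2))
      pmax(mu, floor_s) * exp(rnorm(nrow(df)) * sigma - sigma^2 / 2) +
        (mu - pmax(mu, floor_s))
    }
    design$estimate_s <- pmax(e, floor_s)
  })
  design
}

#' Simulate verbal estimates with a pacemaker-accumulator model
#'
#' Mechanistic counterpart of [linear_clock_model()]: on each trial the
#' pacemaker rate is perturbed multiplicatively (`rate * (1 + eta)`, `eta`
#' zero-mean Gaussian with SD `gain_noise_sd`, truncated positive), the
#' attentional switch transmits pulses with probability `gate_prob`, the
#' accumulator count is Poisson, and the readout divides by
#' `ref_gate * base_rate`. For large pulse counts the rate noise dominates the
#' Poisson noise and the estimate CV approaches `gain_noise_sd` at every
#' duration (scalar timing).
#'
#' @param design Trial table from [generate_design()].
#' @param params A [pacemaker_params()] table covering every cell in `design`.
#' @param seed Integer seed.
#' @param floor_s Minimum reported estimate in seconds.
#' @return `design` with `estimate_s` filled in.
#' @export
pacemaker_accumulator_model <- function(design,
                                        params = default_pacemaker_params(),
                                        seed = 1L, floor_s = 1) {
  stopifnot(is.data.frame(design), all(c("condition", "task", "actual_s")
                                       %in% names(design)))
  df <- join_params(design, params,
                    c("gate_prob", "base_rate", "ref_gate", "gain_noise_sd"),
                    "pacemaker parameters")
  if (any(df$ref_gate == 0)) stop("`ref_gate` must be non-zero.", call. = FALSE)
  withr::with_seed(seed, {
    rate <- df$base_rate * pmax(1 + rnorm(nrow(df), 0, df$gain_noise_sd), 1e-8)
    n_pulses <- rpois(nrow(df), df$gate_prob * rate * df$actual_s)
    design$estimate_s <- pmax(n_pulses / (df$ref_gate * df$base_rate), floor_s)
  })
  design
}

#' Attach simulated math-task performance to trials
#'
#' Adds `correct` (Bernoulli) and `rt_s` (log-normal response time, mean
#' `mean_rt_s`) columns for the arithmetic tasks; other tasks get `NA`. This
#' is deliberately descriptive: it exists so that performance summaries are
#' testable, not to model difficulty mechanistically.
#'
#' @param trials Trial table (any stage).
#' @param params Performance parameter table, see [default_performance_params()].
#' @param seed Integer seed.
#' @return `trials` with `correct` and `rt_s` columns.
#' @export
add_math_performance <- function(trials, params = default_performance_params(),
                                 seed = 1L) {
  stopifnot(is.data.frame(trials))
  idx <- paste(trials$condition, trials$task)
  key <- paste(params$condition, params$task)
  m <- match(idx, key)
  trials$correct <- NA
  trials$rt_s <- NA_real_
  sel <- !is.na(m)
  withr::with_seed(seed, {
    if (any(sel)) {
      acc <- params$accuracy[m[sel]]
      mrt <- params$mean_rt_s[m[sel]]
      sdl <- params$rt_sdlog[m[sel]]
      trials$correct[sel] <- rbinom(sum(sel), 1, acc) == 1
      trials$rt_s[sel] <- exp(rnorm(sum(sel), log(mrt) - sdl^2 / 2, sdl))
    }
  })
  trials
}

#' Generate per-block fatigue, tiredness and temperature records
#'
#' One record per participant x condition x block. Latent values follow
#' `intercept + slope * block_in_session + noise`; Likert variables are
#' rounded to the nearest integer and clipped to 1--7, temperature is rounded
#' to 0.1 degrees C and clipped to a plausible 35--39 band.
#'
#' @param design Trial table from [generate_design()] (used for its
#'   participant/condition/session/block structure).
#' @param trends Trend table, see [default_covariate_trends()].
#' @param seed Integer seed.
#' @return A tibble with columns `participant_id`, `condition`, `session`,
#'   `block`, `block_in_session`, `fatigue`, `tiredness`, `temp_c`.
#' @export
generate_covariates <- function(design, trends = default_covariate_trends(),
                                seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("participant_id", "condition", "block") %in% names(design)))
  keys <- dplyr::distinct(design, .data$participant_id, .data$condition,
                          .data$session, .data$block)
  blocks_per_session <- max(keys$block[keys$session == 1])
  keys$block_in_session <- keys$block - (keys$session - 1L) * blocks_per_session

  latent <- function(var) {
    tr <- trends[trends$variable == var, ]
    m <- match(keys$condition, tr$condition)
    if (anyNA(m)) stop("No covariate trend for condition(s): ",
                       paste(unique(keys$condition[is.na(m)]), collapse = ", "),
                       call. = FALSE)
    tr$intercept[m] + tr$slope[m] * keys$block_in_session +
      rnorm(nrow(keys), 0, tr$noise_sd[m])
  }
  withr::with_seed(seed, {
    keys$fatigue <- pmin(7, pmax(1, round(latent("fatigue"))))
    keys$tiredness <- pmin(7, pmax(1, round(latent("tiredness"))))
    keys$temp_c <- pmin(39, pmax(35, round(latent("temp_c"), 1)))
  })
  tibble::as_tibble(keys)
}
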