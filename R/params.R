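#' Clock parameters for the linear internal-clock generator
#'
#' One row per (condition, task) cell. Under the linear model an interval of
#' true duration `d` is estimated as `e = offset + gain * d + noise`, so the
#' estimation bias `e - d` has intercept `offset` and slope `gain - 1`.
#' `cv` is the coefficient of variation of the noise (SD proportional to the
#' expected estimate, the scalar-timing property); a fraction `outlier_rate`
#' of trials have their noise SD inflated by `outlier_scale`, emulating the
#' occasional wild verbal report that the outlier filter must catch.
#'
#' @param condition,task Character vectors (recycled against each other).
#' @param offset Additive offset in seconds (bias intercept).
#' @param gain Multiplicative clock gain (bias slope is `gain - 1`).
#' @param cv Coefficient of variation of the estimate noise (`>= 0`).
#' @param outlier_rate Probability a trial is a contaminant (`0 <= rate < 0.2`).
#' @param outlier_scale Noise-SD multiplier on contaminant trials.
#' @return A tibble with class `clock_params`.
#' @seealso [default_clock_params()], [linear_clock_model()]
#' @export
clock_params <- function(condition, task, offset, gain,
                         cv = 0.2, outlier_rate = 0.02, outlier_scale = 5) {
  out <- tibble::tibble(
    condition = condition, task = task, offset = offset, gain = gain,
    cv = cv, outlier_rate = outlier_rate, outlier_scale = outlier_scale
  )
  stopifnot(all(out$cv >= 0),
            all(out$outlier_rate >= 0), all(out$outlier_rate < 0.2),
            all(out$outlier_scale > 0),
            !anyDuplicated(out[, c("condition", "task")]))
  class(out) <- c("clock_params", class(out))
  out
}

#' Default clock parameters for the 2 x 4 dual-task design
#'
#' Offsets and gains reproduce the fitted bias lines of the reference study:
#' attending only to time ("look") overestimates by a roughly constant amount;
#' reading is near-veridical; mental arithmetic underestimates progressively
#' with duration, more for hard sums, and every distortion is amplified while
#' walking. `cv = 0.2` puts the relative dispersion at the level of the
#' reference RMSE slopes (0.14-0.23).
#'
#' @param cv,outlier_rate,outlier_scale Shared noise settings for all cells.
#' @return A `clock_params` tibble with eight rows.
#' @export
default_clock_params <- function(cv = 0.2, outlier_rate = 0.02,
                                 outlier_scale = 5) {
  clock_params(
    condition = rep(c("sitting", "walking"), each = 4),
    task = rep(c("look", "read", "solve_simple", "solve_hard"), 2),
    offset = c(6.4, 4.8, 2.8, 1.2,
               8.9, 5.7, 3.3, 1.8),
    gain = 1 + c(0.005, -0.09, -0.2, -0.3,
                 0.01, -0.1, -0.3, -0.4),
    cv = cv, outlier_rate = outlier_rate, outlier_scale = outlier_scale
  )
}

#' Pacemaker-accumulator (attentional gate) parameters
#'
#' Mechanistic generator: a pacemaker emits pulses at `base_rate` per second;
#' an attentional switch transmits them with probability `gate_prob` (lower
#' when a concurrent task diverts attention from timing); the accumulator
#' count is read out against a calibration gate `ref_gate`, so the expected
#' estimate is `(gate_prob / ref_gate) * d`. Multiplicative trial-to-trial
#' clock-rate noise with SD `gain_noise_sd` produces the scalar property once
#' it dominates Poisson counting noise.
#'
#' @param condition,task Character vectors (recycled).
#' @param base_rate Pacemaker rate, pulses per second (`> 0`).
#' @param gate_prob Probability the switch transmits pulses (`0 < p <= 1`).
#' @param ref_gate Calibration gate probability used by the readout (`> 0`).
#' @param gain_noise_sd SD of multiplicative clock-rate noise (`>= 0`).
#' @return A tibble with class `pacemaker_params`.
#' @export
pacemaker_params <- function(condition, task, gate_prob,
                             base_rate = 50, ref_gate = 0.9,
                             gain_noise_sd = 0.2) {
  out <- tibble::tibble(
    condition = condition, task = task, gate_prob = gate_prob,
    base_rate = base_rate, ref_gate = ref_gate,
    gain_noise_sd = gain_noise_sd
  )
  stopifnot(all(out$gate_prob > 0), all(out$gate_prob <= 1),
            all(out$base_rate > 0), all(out$gain_noise_sd >= 0),
            !anyDuplicated(out[, c("condition", "task")]))
  if (any(out$ref_gate == 0)) stop("`ref_gate` must be non-zero.", call. = FALSE)
  class(out) <- c("pacemaker_params", class(out))
  out
}

#' Default pacemaker parameters matched to the linear-clock gains
#'
#' Gate probabilities are proportional to the linear-model gains with the
#' "read" task as the calibration reference (`ref_gate = 0.9`), so reading is
#' near-veridical and every other cell reproduces the same relative bias slope
#' `gate_prob / ref_gate - 1` as the linear generator (the pacemaker has no
#' additive offset).
#'
#' @inheritParams pacemaker_params
#' @return A `pacemaker_params` tibble with eight rows.
#' @export
default_pacemaker_params <- function(base_rate = 50, ref_gate = 0.9,
                                     gain_noise_sd = 0.2) {
  cp <- default_clock_params()
  pacemaker_params(
    condition = cp$condition, task = cp$task,
    gate_prob = pmin(1, ref_gate * cp$gain),
    base_rate = base_rate, ref_gate = ref_gate,
    gain_noise_sd = gain_noise_sd
  )
}

#' Default math-task performance parameters
#'
#' Accuracy is Bernoulli and response time log-normal per (condition, task)
#' cell; these are descriptive knobs (no mechanistic difficulty model) set to
#' the reference study's cell means: near-ceiling accuracy for simple sums,
#' lower and walking-impaired accuracy for hard sums, and slower responses
#' while walking.
#'
#' @return A tibble with columns `condition`, `task`, `accuracy`, `mean_rt_s`,
#'   `rt_sdlog`.
#' @export
default_performance_params <- function() {
  tibble::tibble(
    condition = rep(c("sitting", "walking"), each = 2),
    task = rep(c("solve_simple", "solve_hard"), 2),
    accuracy = c(0.996, 0.947, 0.996, 0.913),
    mean_rt_s = c(1.45, 3.02, 1.62, 3.16),
    rt_sdlog = 0.3
  )
}

#' Default per-block covariate trends
#'
#' Latent linear-in-block trends for self-rated physical fatigue and mental
#' tiredness (7-point Likert) and body temperature (degrees C): fatigue rises
#' with block only while walking, tiredness rises in both conditions,
#' temperature is flat. Intercepts and slopes follow the reference study's
#' block regressions; noise SDs are chosen at the scale of the reported
#' between-block variation.
#'
#' @return A tibble with columns `variable`, `condition`, `intercept`,
#'   `slope`, `noise_sd`.
#' @export
default_covariate_trends <- function() {
  tibble::tibble(
    variable = rep(c("fatigue", "tiredness", "temp_c"), each = 2),
    condition = rep(c("sitting", "walking"), 3),
    intercept = c(1.39, 1.55, 1.57, 1.74, 36.7, 36.5),
    slope = c(0.01, 0.15, 0.13, 0.16, 0, 0),
    noise_sd = c(0.3, 0.4, 0.3, 0.3, 0.1, 0.1)
  )
}
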