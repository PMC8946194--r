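#' Pipeline configuration
#'
#' Bundles everything a reproducible run needs: the design, the generative
#' model and its parameters, the filter width, bin width, bootstrap size and
#' the master seed. A run is fully determined by the config (all stage seeds
#' are derived from `seed`). `input_csv` switches the pipeline from
#' simulation to ingesting an existing trial file.
#'
#' @param design A [design_spec()].
#' @param model `"linear"` or `"pacemaker"`.
#' @param clock_params [clock_params()] table for the linear model.
#' @param pacemaker [pacemaker_params()] table for the pacemaker model.
#' @param performance Performance parameter table (or `NULL` to skip).
#' @param covariates Covariate trend table (or `NULL` to skip).
#' @param filter_k Outlier-filter width in SD units.
#' @param bin_width Bias/RMSE bin width in seconds (2 or 3).
#' @param rmse_se_B Bootstrap replicates for per-bin RMSE SEs (0 disables;
#'   RMSE fits are then unweighted).
#' @param noise Noise law for the linear model (`"gaussian"`/`"lognormal"`).
#' @param seed Master integer seed.
#' @param input_csv Optional path to a trial CSV to analyse instead of
#'   simulating.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_spec(),
                            model = c("linear", "pacemaker"),
                            clock_params = default_clock_params(),
                            pacemaker = default_pacemaker_params(),
                            performance = default_performance_params(),
                            covariates = default_covariate_trends(),
                            filter_k = 3, bin_width = 2, rmse_se_B = 0,
                            noise = "gaussian",
                            seed = 1L, input_csv = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "design_spec"), filter_k > 0,
            bin_width %in% c(2, 3), rmse_se_B >= 0)
  structure(list(design = design, model = model, clock_params = clock_params,
                 pacemaker = pacemaker, performance = performance,
                 covariates = covariates, filter_k = filter_k,
                 bin_width = bin_width, rmse_se_B = rmse_se_B, noise = noise,
                 seed = as.integer(seed), input_csv = input_csv),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Reconstructs a [pipeline_config()] from a JSON file holding any subset of
#' the config fields; parameter tables are given as arrays of per-cell
#' objects (one per condition x task).
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_args <- raw$design %||% list()
  args <- list(
    design = do.call(design_spec, design_args),
    model = raw$model %||% "linear",
    filter_k = raw$filter_k %||% 3,
    bin_width = raw$bin_width %||% 2,
    rmse_se_B = raw$rmse_se_B %||% 0,
    noise = raw$noise %||% "gaussian",
    seed = raw$seed %||% 1L,
    input_csv = raw$input_csv
  )
  if (!is.null(raw$clock_params)) {
    args$clock_params <- do.call(clock_params, as.list(raw$clock_params))
  }
  if (!is.null(raw$pacemaker)) {
    args$pacemaker <- do.call(pacemaker_params, as.list(raw$pacemaker))
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate/filter/bin/fit/test pipeline
#'
#' Executes the analysis chain in order: simulate (or ingest) trials, compute
#' biases and filter outliers per cell, summarise cells, bin over short
#' duration windows, fit bias and RMSE lines, estimate coefficients of
#' variation, run cell-wise accuracy tests, compute motor/cognitive effect
#' summaries, summarise math-task performance, and regress covariates on
#' block number. All randomness derives from `config$seed`, so a config
#' fully determines every number in the report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report JSON and tidy
#'   CSV artifacts (trials, cell summaries, binned series) are written there.
#' @return A `run_report`: a named list of tibbles/lists covering every
#'   analysis stage plus provenance (seed, model, filter tallies).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (!is.null(config$input_csv)) {
    trials <- ingest_trials(config$input_csv)
    covariates <- NULL
  } else {
    spec <- config$design
    spec$rng_seed <- seed
    design <- generate_design(spec)
    trials <- switch(config$model,
      linear = linear_clock_model(design, config$clock_params,
                                  seed = seed + 1L, noise = config$noise),
      pacemaker = pacemaker_accumulator_model(design, config$pacemaker,
                                              seed = seed + 1L)
    )
    if (!is.null(config$performance)) {
      trials <- add_math_performance(trials, config$performance,
                                     seed = seed + 2L)
    }
    covariates <- if (!is.null(config$covariates)) {
      generate_covariates(design, config$covariates, seed = seed + 3L)
    }
  }

  bias <- compute_bias(trials, filter = TRUE, k = config$filter_k)
  cells <- cell_summaries(bias)
  bins <- make_bins(bias, width = config$bin_width,
                    rmse_se_B = config$rmse_se_B, seed = seed + 4L)
  bias_fits <- fit_bias_line(bins)
  rmse_fits <- fit_rmse_line(bins, mode = "vs_duration")
  cv_fits <- fit_rmse_line(bins, mode = "vs_estimate")

  cv_comparisons <- cv_fits |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      compare_slopes(dplyr::mutate(df, condition = key$condition),
                     slope_col = "cv", se_col = "cv_se")
    }) |>
    dplyr::ungroup()
  slope_condition_comparisons <- bias_fits |>
    dplyr::group_by(.data$task) |>
    dplyr::group_modify(function(df, key) {
      compare_slopes(dplyr::mutate(df, task = key$task))
    }) |>
    dplyr::ungroup()

  wilcoxon <- accuracy_tests(bias)
  effects <- effect_summaries(cells)
  performance <- if ("correct" %in% names(trials) &&
                       any(!is.na(trials$correct))) {
    performance_summaries(trials)
  }
  covariate_trends <- if (!is.null(covariates)) {
    covariates |>
      tidyr::pivot_longer(c("fatigue", "tiredness", "temp_c"),
                          names_to = "variable", values_to = "value") |>
      dplyr::group_by(.data$condition, .data$variable,
                      .data$block_in_session) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop_last") |>
      dplyr::group_modify(function(df, key) {
        bt <- block_trend_regression(df$block_in_session, df$value)
        tibble::tibble(slope = bt$slope, t = bt$t, df = bt$df,
                       p_value = bt$p_value, r_squared = bt$r_squared)
      }) |>
      dplyr::ungroup()
  }

  filter_summary <- attr(bias, "filter_summary")
  report <- structure(list(
    provenance = list(seed = seed, model = config$model,
                      filter_k = config$filter_k,
                      bin_width = config$bin_width,
                      n_trials = nrow(trials),
                      n_filtered_out = sum(!bias$kept),
                      package_version =
                        as.character(utils::packageVersion("prospectime"))),
    cells = cells,
    bias_fits = bias_fits,
    rmse_fits = rmse_fits,
    cv_fits = cv_fits,
    cv_comparisons = cv_comparisons,
    slope_condition_comparisons = slope_condition_comparisons,
    wilcoxon = wilcoxon,
    effects = effects,
    performance = performance,
    covariate_trends = covariate_trends,
    filter_summary = filter_summary,
    dropped_bins = attr(bins, "dropped_bins"),
    trials = trials,
    bins = bins
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  p <- x$provenance
  cat("prospectime run report (seed", p$seed, ", model", p$model, ")\n")
  cat(" ", p$n_trials, "trials;", p$n_filtered_out, "removed by the",
      paste0(p$filter_k, "-SD"), "pseudomedian filter\n")
  cat("  Bias fits (slope +/- SE per condition/task):\n")
  f <- x$bias_fits
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %-8s %-12s slope %+6.3f +/- %.3f  intercept %5.2f +/- %.2f  chisq(%d) = %.1f\n",
                f$condition[i], f$task[i], f$slope[i], f$slope_se[i],
                f$intercept[i], f$intercept_se[i], f$df[i], f$chisq[i]))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Serialises the report as `report.json` plus tidy CSVs (`trials.csv`,
#' `cells.csv`, `bins.csv`) under `out_dir`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- report[c("provenance", "cells", "bias_fits", "rmse_fits",
                   "cv_fits", "cv_comparisons",
                   "slope_condition_comparisons", "wilcoxon",
                   "covariate_trends", "filter_summary")]
  json$effects <- unclass(report$effects)
  json$performance <- report$performance
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_trials(report$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(report$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bins, file.path(out_dir, "bins.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
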