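#' Per-trial estimation bias with optional outlier filtering
#'
#' Computes the estimation bias `estimate_s - actual_s` (positive =
#' overestimation) for every trial and, when `filter = TRUE`, applies the
#' pseudomedian-centred outlier filter ([filter_outliers()]) to the estimates
#' of each (condition, task, nominal interval) cell, pooling trials across
#' participants. Filtered-out trials are retained in the table with
#' `kept = FALSE` so that bootstrap procedures can re-run the filter on the
#' raw data; all downstream averaging uses kept trials only.
#'
#' @param trials Trial table with `estimate_s` set.
#' @param filter Apply the per-cell outlier filter (default `TRUE`).
#' @param k Filter width in SD units (default 3).
#' @return A `bias_table`: the input tibble plus `bias_s` and `kept` columns,
#'   with a `filter_summary` attribute (one row per cell: n, n_removed,
#'   pseudomedian, sd_used, bounds).
#' @export
compute_bias <- function(trials, filter = TRUE, k = 3) {
  stopifnot(is.data.frame(trials),
            all(c("condition", "task", "nominal_s", "actual_s", "estimate_s")
                %in% names(trials)))
  if (anyNA(trials$estimate_s)) {
    stop("`estimate_s` contains missing values; run a response model first.",
         call. = FALSE)
  }
  trials$bias_s <- trials$estimate_s - trials$actual_s
  trials$kept <- TRUE
  summaries <- NULL
  if (filter) {
    cell_id <- paste(trials$condition, trials$task, trials$nominal_s)
    pieces <- split(seq_len(nrow(trials)), cell_id)
    rows <- vector("list", length(pieces))
    for (i in seq_along(pieces)) {
      idx <- pieces[[i]]
      fr <- filter_outliers(trials$estimate_s[idx], k)
      trials$kept[idx] <- fr$kept_idx
      key <- trials[idx[1], c("condition", "task", "nominal_s")]
      rows[[i]] <- tibble::tibble(
        key, n = length(idx), n_removed = length(fr$removed),
        pseudomedian = fr$pseudomedian, sd_used = fr$sd_used,
        lower_bound = fr$lower_bound, upper_bound = fr$upper_bound)
    }
    summaries <- dplyr::bind_rows(rows)
  }
  out <- tibble::as_tibble(trials)
  attr(out, "filter_summary") <- summaries
  attr(out, "filter_k") <- if (filter) k else NA_real_
  class(out) <- c("bias_table", class(out))
  out
}

#' Cell-level summary of estimates (reference-table analogue)
#'
#' Mean estimated duration per (condition, task, nominal interval), computed
#' as the mean of participant means with the standard error taken across
#' participants — the layout conventionally reported for this design. Mean
#' bias is summarised the same way. Only trials kept by the filter enter.
#'
#' @param bias_table Output of [compute_bias()].
#' @return Tibble with `condition`, `task`, `nominal_s`, `n_participants`,
#'   `mean_estimate`, `se_estimate`, `mean_bias`, `se_bias`.
#' @export
cell_summaries <- function(bias_table) {
  stopifnot(is.data.frame(bias_table), "kept" %in% names(bias_table))
  bias_table |>
    dplyr::filter(.data$kept) |>
    dplyr::group_by(.data$condition, .data$task, .data$nominal_s,
                    .data$participant_id) |>
    dplyr::summarise(est = mean(.data$estimate_s), b = mean(.data$bias_s),
                     .groups = "drop_last") |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      mean_estimate = mean(.data$est),
      se_estimate = sd(.data$est) / sqrt(dplyr::n()),
      mean_bias = mean(.data$b),
      se_bias = sd(.data$b) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

bin_starts <- function(window, width) {
  seq.int(window[1], window[length(window)], by = width)
}

#' Bin biases over short duration windows
#'
#' Partitions each nominal interval's integer jitter window into bins of
#' `width` seconds, anchored at the window minimum (the final bin of an
#' odd-width window holds a single duration value), and summarises kept
#' trials per (condition, task, bin): mean bias, its standard error
#' (SD / sqrt(n)), the RMSE (within-bin root-mean-square deviation of the
#' bias about the bin mean by default, or about zero — i.e. about the true
#' duration — with `rmse_about = "truth"`), and the mean estimate. With the
#' default 2-s width and 10% windows on 15/30/60/90/120 s this yields
#' 3 + 4 + 7 + 10 + 13 = 37 bins per (condition, task).
#'
#' Bins with fewer than two kept trials are dropped from the output (they
#' carry no dispersion information) and reported in the `dropped_bins`
#' attribute.
#'
#' @param bias_table Output of [compute_bias()].
#' @param width Bin width in seconds, 2 or 3.
#' @param rmse_about `"bin_mean"` (default; within-bin dispersion, the
#'   uncertainty reading) or `"truth"` (RMS bias about zero).
#' @param se_pooling How the SD entering `se_bias = SD / sqrt(n)` is
#'   estimated: `"cell"` (default) pools the within-bin variance over all
#'   bins of the same nominal-interval cell — under scalar timing the noise
#'   scale is constant across a +/-10% jitter window, and pooling keeps the
#'   fit weights stable when bins hold few trials; `"bin"` uses each bin's
#'   own SD.
#' @param rmse_se_B Per-bin RMSE standard errors (`rmse_se` column) default
#'   to the delta-method value `sd / sqrt(2 (n - 1))`, with the SD scale
#'   taken from the same pooling rule as `se_bias`. If `rmse_se_B` is
#'   positive they are instead bootstrapped through the whole process: each
#'   cell's raw trials are resampled, re-filtered and re-binned
#'   `rmse_se_B` times.
#' @param seed Seed for the RMSE bootstrap.
#' @param jitter_fraction Jitter fraction defining the windows (default 0.10).
#' @return A `binned_series` tibble with columns `condition`, `task`,
#'   `nominal_s`, `bin_start`, `bin_center`, `n`, `mean_bias`, `se_bias`,
#'   `rmse`, `mean_estimate` (and `rmse_se` when bootstrapped).
#' @export
make_bins <- function(bias_table, width = 2,
                      rmse_about = c("bin_mean", "truth"),
                      se_pooling = c("cell", "bin"),
                      rmse_se_B = 0, seed = 1L, jitter_fraction = 0.10) {
  rmse_about <- match.arg(rmse_about)
  se_pooling <- match.arg(se_pooling)
  stopifnot(width %in% c(2, 3), is.data.frame(bias_table),
            all(c("condition", "task", "nominal_s", "actual_s", "bias_s",
                  "kept") %in% names(bias_table)))
  rmse_fun <- function(b) {
    if (rmse_about == "bin_mean") sqrt(mean((b - mean(b))^2))
    else sqrt(mean(b^2))
  }
  assign_bins <- function(df) {
    bounds <- vapply(df$nominal_s, window_bounds, numeric(2),
                     jitter_fraction = jitter_fraction)
    lo <- bounds[1, ]
    hi <- bounds[2, ]
    start <- lo + width * ((df$actual_s - lo) %/% width)
    end <- pmin(start + width - 1, hi)
    df$bin_start <- start
    df$bin_center <- (start + end) / 2
    df
  }
  summarise_bins <- function(df) {
    out <- df |>
      dplyr::group_by(.data$condition, .data$task, .data$nominal_s,
                      .data$bin_start, .data$bin_center) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_bias = mean(.data$bias_s),
        ss_within = sum((.data$bias_s - mean(.data$bias_s))^2),
        se_bias = sd(.data$bias_s) / sqrt(dplyr::n()),
        rmse = rmse_fun(.data$bias_s),
        mean_estimate = mean(.data$estimate_s),
        .groups = "drop"
      )
    if (se_pooling == "cell") {
      out <- out |>
        dplyr::group_by(.data$condition, .data$task, .data$nominal_s) |>
        dplyr::mutate(se_bias = sqrt(sum(.data$ss_within) /
                                       pmax(1, sum(.data$n) - dplyr::n())) /
                        sqrt(.data$n)) |>
        dplyr::ungroup()
    }
    out$ss_within <- NULL
    out
  }
  kept <- assign_bins(bias_table[bias_table$kept, ])
  out <- summarise_bins(kept)
  dropped <- out[out$n < 2, ]
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " bin(s) with fewer than 2 trials dropped.")
  }
  out <- out[out$n >= 2, ]
  # delta-method SE of an SD-like statistic; the noise scale comes from the
  # cell-pooled SD under se_pooling = "cell" (a bin's own tiny-n RMSE is too
  # unstable to set its weight)
  scale_sd <- if (se_pooling == "cell") out$se_bias * sqrt(out$n) else out$rmse
  out$rmse_se <- scale_sd / sqrt(2 * (out$n - 1))

  if (rmse_se_B > 0) {
    out$rmse_se <- NULL
    k <- attr(bias_table, "filter_k")
    if (is.null(k) || is.na(k)) k <- 3
    cell_id <- paste(bias_table$condition, bias_table$task,
                     bias_table$nominal_s)
    boot <- withr::with_seed(seed, {
      lapply(split(seq_len(nrow(bias_table)), cell_id), function(idx) {
        cell <- bias_table[idx, ]
        reps <- lapply(seq_len(rmse_se_B), function(b) {
          rs <- cell[sample.int(nrow(cell), nrow(cell), replace = TRUE), ]
          fr <- filter_outliers(rs$estimate_s, k)
          rs <- assign_bins(rs[fr$kept_idx, ])
          rs |>
            dplyr::group_by(.data$bin_start) |>
            dplyr::summarise(rmse = rmse_fun(.data$bias_s), n = dplyr::n(),
                             .groups = "drop") |>
            dplyr::filter(.data$n >= 2)
        })
        dplyr::bind_rows(reps) |>
          dplyr::group_by(.data$bin_start) |>
          dplyr::summarise(rmse_se = sd(.data$rmse), .groups = "drop") |>
          dplyr::mutate(condition = cell$condition[1], task = cell$task[1],
                        nominal_s = cell$nominal_s[1])
      })
    })
    out <- dplyr::left_join(out, dplyr::bind_rows(boot),
                            by = c("condition", "task", "nominal_s",
                                   "bin_start"))
  }
  attr(out, "dropped_bins") <- dropped
  attr(out, "rmse_about") <- rmse_about
  class(out) <- c("binned_series", class(out))
  out
}
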