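#' Coefficient of variation with a whole-process bootstrap SE
#'
#' Point estimates are the through-origin weighted fits of per-bin RMSE
#' against per-bin mean estimate ([fit_rmse_line()] in `vs_estimate` mode).
#' The default standard error is the fit SE; `se_method = "bootstrap"`
#' instead propagates the *whole process* — trials are resampled with
#' replacement within each (condition, task, interval) cell, the pseudomedian
#' filter, the binning and the through-origin fit are re-run on every
#' replicate, and the SE is the SD of the replicate CVs. The bootstrap route
#' captures two sources of uncertainty the fit SE does not: the randomness of
#' the filter bounds (shared by all bins of a cell, which correlates their
#' RMSE errors) and the heavy tails left by surviving contaminant trials.
#'
#' @param bias_table Output of [compute_bias()] (must retain removed trials,
#'   i.e. come from the standard filtered pipeline).
#' @param width Bin width in seconds (2 or 3).
#' @param se_method `"fit"` (through-origin weighted slope SE, default) or
#'   `"bootstrap"` (whole-process resampling).
#' @param B Bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return Tibble with one row per (condition, task): `cv`, `cv_se`,
#'   `se_method` (and `B` for the bootstrap route).
#' @export
estimate_cv <- function(bias_table, width = 2,
                        se_method = c("fit", "bootstrap"),
                        B = 200, seed = 1L) {
  se_method <- match.arg(se_method)
  k <- attr(bias_table, "filter_k")
  if (is.null(k) || is.na(k)) k <- 3
  point <- fit_rmse_line(suppressMessages(make_bins(bias_table, width)),
                         mode = "vs_estimate")
  out <- point[, c("condition", "task", "cv", "cv_se")]
  out$se_method <- se_method
  if (se_method == "fit") return(out)

  stopifnot(B >= 50)
  cell_id <- paste(bias_table$condition, bias_table$task,
                   bias_table$nominal_s)
  cells <- split(seq_len(nrow(bias_table)), cell_id)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- unlist(lapply(cells, function(i)
        i[sample.int(length(i), length(i), replace = TRUE)]))
      rs <- compute_bias(bias_table[idx, ], filter = TRUE, k = k)
      cvb <- fit_rmse_line(suppressMessages(make_bins(rs, width)),
                           mode = "vs_estimate")
      cvb[, c("condition", "task", "cv")]
    })
  })
  boot_se <- dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$condition, .data$task) |>
    dplyr::summarise(cv_se = sd(.data$cv), .groups = "drop")
  out$cv_se <- boot_se$cv_se[match(paste(out$condition, out$task),
                                   paste(boot_se$condition, boot_se$task))]
  out$B <- as.integer(B)
  out
}
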