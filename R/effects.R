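#' Cell-wise accuracy tests of the estimation bias
#'
#' One-sample Wilcoxon signed-rank test of bias against zero for every
#' (condition, task, nominal interval) cell, on trials kept by the filter.
#' p-values are Bonferroni-adjusted within each motor condition (the family
#' is the set of task x interval cells reported together for a condition).
#' Cells with fewer than `min_n` trials are flagged.
#'
#' @param bias_table Output of [compute_bias()].
#' @param alpha Significance level applied to adjusted p-values.
#' @param min_n Minimum trials per cell before the cell is flagged as tiny.
#' @return Tibble with one row per cell: `V`, `n_effective`, `method`,
#'   `p_value`, `p_adjusted`, `significant`, `mean_bias`, `small_cell`.
#' @export
accuracy_tests <- function(bias_table, alpha = 0.05, min_n = 5) {
  stopifnot(is.data.frame(bias_table), "kept" %in% names(bias_table))
  res <- bias_table |>
    dplyr::filter(.data$kept) |>
    dplyr::group_by(.data$condition, .data$task, .data$nominal_s) |>
    dplyr::group_modify(function(df, key) {
      wt <- wilcoxon_signed_rank(df$bias_s)
      tibble::tibble(V = wt$statistic, n_effective = wt$n_effective,
                     method = wt$method, p_value = wt$p_value,
                     mean_bias = mean(df$bias_s),
                     small_cell = nrow(df) < min_n)
    }) |>
    dplyr::ungroup()
  res |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(p_adjusted = bonferroni_adjust(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_adjusted < alpha)
}

#' Percentual motor and cognitive effects on time estimation
#'
#' Quantifies, relative to the nominal interval, how much walking and
#' cognitive load shift the mean estimate. The motor effect isolates walking
#' using the no-load "look" task:
#' `(mean estimate walking - mean estimate sitting) / T`. The cognitive
#' effect isolates task load in the sitting condition:
#' `(mean estimate look - mean estimate solve) / T`, for each solve task.
#' Reported per interval together with the mean and maximum across intervals
#' (the cognitive mean/max pool both solve tasks).
#'
#' @param cell_means Tibble with columns `condition`, `task`, `nominal_s`,
#'   `mean_estimate` — e.g. [cell_summaries()] output or
#'   [reference_cell_means()].
#' @param look_task,solve_tasks Task labels used for the contrasts.
#' @return An object of class `effect_summary`: list with `motor` (tibble of
#'   per-interval percent effects), `motor_mean_pct`, `motor_max_pct`,
#'   `cognitive` (per solve task and interval), `cognitive_mean_pct`,
#'   `cognitive_max_pct`. Percentages are signed: positive motor = longer
#'   estimates while walking; positive cognitive = shorter estimates under
#'   load.
#' @export
effect_summaries <- function(cell_means, look_task = "look",
                             solve_tasks = c("solve_simple", "solve_hard")) {
  need <- c("condition", "task", "nominal_s", "mean_estimate")
  stopifnot(is.data.frame(cell_means), all(need %in% names(cell_means)))
  cm <- cell_means[, need]

  pull_cell <- function(cond, task) {
    sub <- cm[cm$condition == cond & cm$task == task, ]
    sub[order(sub$nominal_s), ]
  }
  look_sit <- pull_cell("sitting", look_task)
  look_walk <- pull_cell("walking", look_task)

  motor <- NULL
  if (nrow(look_sit) > 0 && nrow(look_walk) > 0) {
    joined <- dplyr::inner_join(look_sit, look_walk, by = "nominal_s",
                                suffix = c("_sit", "_walk"))
    motor <- tibble::tibble(
      nominal_s = joined$nominal_s,
      percent = 100 * (joined$mean_estimate_walk - joined$mean_estimate_sit) /
        joined$nominal_s
    )
  } else {
    warning("Missing look-task cells; motor effect not computed.")
  }

  cog <- lapply(solve_tasks, function(tk) {
    solve_sit <- pull_cell("sitting", tk)
    if (nrow(solve_sit) == 0 || nrow(look_sit) == 0) {
      warning("Missing sitting cells for task ", tk,
              "; cognitive effect skipped.")
      return(NULL)
    }
    joined <- dplyr::inner_join(look_sit, solve_sit, by = "nominal_s",
                                suffix = c("_look", "_solve"))
    tibble::tibble(
      task = tk, nominal_s = joined$nominal_s,
      percent = 100 * (joined$mean_estimate_look -
                         joined$mean_estimate_solve) / joined$nominal_s
    )
  })
  cognitive <- dplyr::bind_rows(cog)

  structure(list(
    motor = motor,
    motor_mean_pct = if (!is.null(motor)) mean(motor$percent) else NA_real_,
    motor_max_pct = if (!is.null(motor))
      motor$percent[which.max(abs(motor$percent))] else NA_real_,
    cognitive = cognitive,
    cognitive_mean_pct = if (nrow(cognitive)) mean(cognitive$percent)
      else NA_real_,
    cognitive_max_pct = if (nrow(cognitive))
      cognitive$percent[which.max(abs(cognitive$percent))] else NA_real_
  ), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("Motor effect (look task): mean %.1f%%, max %.1f%%\n",
              x$motor_mean_pct, x$motor_max_pct))
  cat(sprintf("Cognitive effect (sitting): mean %.1f%%, max %.1f%%\n",
              x$cognitive_mean_pct, x$cognitive_max_pct))
  invisible(x)
}

#' Descriptive math-task performance summaries
#'
#' Mean accuracy (percent correct) and mean response time per (condition,
#' task), with standard errors across participants, plus the per-task paired
#' walking-minus-sitting response-time differences and a paired t-test
#' comparing those differences between the two solve tasks. Inferential
#' ANOVA-style modelling is deliberately out of scope.
#'
#' @param trials Trial table carrying `correct` and `rt_s` (see
#'   [add_math_performance()]).
#' @return List with `cells` (per condition x task summary) and `rt_paired`
#'   (per-task mean paired RT difference with t-test, and the between-task
#'   comparison of the differences).
#' @export
performance_summaries <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("correct", "rt_s") %in% names(trials)))
  perf <- trials[!is.na(trials$correct), ]
  if (nrow(perf) == 0) stop("No trials carry performance data.", call. = FALSE)
  by_part <- perf |>
    dplyr::group_by(.data$condition, .data$task, .data$participant_id) |>
    dplyr::summarise(acc = 100 * mean(.data$correct),
                     rt = mean(.data$rt_s), .groups = "drop")
  cells <- by_part |>
    dplyr::group_by(.data$condition, .data$task) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      accuracy_pct = mean(.data$acc),
      accuracy_se = sd(.data$acc) / sqrt(dplyr::n()),
      mean_rt_s = mean(.data$rt),
      rt_se = sd(.data$rt) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(by_part, names_from = "condition",
                             values_from = c("acc", "rt"))
  rt_paired <- NULL
  if (all(c("rt_sitting", "rt_walking") %in% names(wide))) {
    diffs <- wide |>
      dplyr::mutate(rt_diff = .data$rt_walking - .data$rt_sitting)
    per_task <- diffs |>
      dplyr::group_by(.data$task) |>
      dplyr::summarise(
        mean_rt_diff_s = mean(.data$rt_diff),
        se = sd(.data$rt_diff) / sqrt(dplyr::n()),
        t = mean(.data$rt_diff) / (sd(.data$rt_diff) / sqrt(dplyr::n())),
        df = dplyr::n() - 1L,
        .groups = "drop"
      ) |>
      dplyr::mutate(p_value = 2 * pt(-abs(.data$t), .data$df))
    tasks <- unique(diffs$task)
    between <- NULL
    if (length(tasks) == 2) {
      d_wide <- tidyr::pivot_wider(diffs[, c("participant_id", "task",
                                             "rt_diff")],
                                   names_from = "task",
                                   values_from = "rt_diff")
      dd <- d_wide[[tasks[1]]] - d_wide[[tasks[2]]]
      dd <- dd[!is.na(dd)]
      if (length(dd) >= 2) {
        tt <- stats::t.test(dd)
        between <- tibble::tibble(
          contrast = paste(tasks[1], "vs", tasks[2]),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value)
      }
    }
    rt_paired <- list(per_task = per_task, between_tasks = between)
  }
  list(cells = cells, rt_paired = rt_paired)
}
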