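#' Hodges-Lehmann pseudomedian
#'
#' The median of all Walsh averages `(x[i] + x[j]) / 2` over `i <= j` — the
#' one-sample Hodges-Lehmann estimator, a robust location estimate used here
#' to centre the outlier filter on long-tailed estimate distributions.
#'
#' @param x Non-empty numeric vector with no missing values.
#' @return The pseudomedian (length-1 numeric).
#' @export
#' @examples
#' hodges_lehmann(c(1, 2, 6))  # 2.75
hodges_lehmann <- function(x) {
  if (length(x) == 0) stop("`x` must be non-empty.", call. = FALSE)
  if (anyNA(x)) stop("`x` must not contain missing values.", call. = FALSE)
  if (length(x) == 1) return(as.numeric(x))
  w <- outer(x, x, "+") / 2
  median(w[upper.tri(w, diag = TRUE)])
}

#' Pseudomedian-centred outlier filter
#'
#' Single-pass filter: values farther than `k` raw-sample standard deviations
#' from the Hodges-Lehmann pseudomedian are removed. The SD is the ordinary
#' (n - 1) standard deviation of the *unfiltered* sample and the bounds are
#' computed once, so re-filtering the kept values with the same bounds removes
#' nothing more. Removal uses a strict inequality; values exactly on a bound
#' are kept. Samples of size < 2 pass through untouched.
#'
#' @param x Numeric vector.
#' @param k Width of the acceptance band in SD units (default 3).
#' @return An object of class `filter_result`: a list with `kept`, `removed`,
#'   `kept_idx` (logical mask on `x`), `pseudomedian`, `sd_used`,
#'   `lower_bound`, `upper_bound`.
#' @export
filter_outliers <- function(x, k = 3) {
  stopifnot(k > 0)
  if (anyNA(x)) stop("`x` must not contain missing values.", call. = FALSE)
  if (length(x) < 2) {
    return(structure(list(kept = as.numeric(x), removed = numeric(),
                          kept_idx = rep(TRUE, length(x)),
                          pseudomedian = if (length(x)) hodges_lehmann(x) else NA_real_,
                          sd_used = NA_real_,
                          lower_bound = -Inf, upper_bound = Inf),
                     class = "filter_result"))
  }
  pm <- hodges_lehmann(x)
  s <- sd(x)
  if (s == 0) {
    keep <- rep(TRUE, length(x))
  } else {
    keep <- abs(x - pm) <= k * s
  }
  structure(list(kept = x[keep], removed = x[!keep], kept_idx = keep,
                 pseudomedian = pm, sd_used = s,
                 lower_bound = pm - k * s, upper_bound = pm + k * s),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Pseudomedian outlier filter: kept", length(x$kept), "of",
      length(x$kept) + length(x$removed), "values\n")
  cat(sprintf("  pseudomedian %.4g, SD %.4g, bounds [%.4g, %.4g]\n",
              x$pseudomedian, x$sd_used, x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Bootstrap variance of a filtered-sample statistic
#'
#' Estimates the sampling uncertainty of a statistic computed after outlier
#' filtering by bootstrapping the *whole process*: each resample is drawn with
#' replacement from the raw (unfiltered) sample, the pseudomedian filter is
#' re-applied, and the statistic is evaluated on the kept values. Resamples in
#' which fewer than two values survive the filter are redrawn (and counted),
#' so the statistic stays defined without silently biasing the replicates.
#'
#' @param x Raw numeric sample.
#' @param statistic Function of a numeric vector; default `stats::var`, the
#'   variance after filtering.
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; results are reproducible given `seed`.
#' @param k Filter width passed to [filter_outliers()].
#' @return An object of class `bootstrap_variance`: list with
#'   `point_estimate` (statistic on the filtered original sample),
#'   `se_of_estimate` (SD of the replicates), `B`, `seed`, `n_redrawn`.
#' @export
bootstrap_variance <- function(x, statistic = stats::var, B = 1000,
                               seed = 1L, k = 3) {
  stopifnot(B >= 100, length(x) >= 2)
  point <- statistic(filter_outliers(x, k)$kept)
  n <- length(x)
  n_redrawn <- 0L
  withr::with_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      repeat {
        kept <- filter_outliers(x[sample.int(n, n, replace = TRUE)], k)$kept
        if (length(kept) >= 2) return(statistic(kept))
        n_redrawn <<- n_redrawn + 1L
        if (n_redrawn > 100L * B) {
          stop("Bootstrap resamples keep collapsing under the filter.",
               call. = FALSE)
        }
      }
    }, numeric(1))
  })
  structure(list(point_estimate = point,
                 se_of_estimate = sd(reps),
                 B = as.integer(B), seed = as.integer(seed),
                 n_redrawn = n_redrawn),
            class = "bootstrap_variance")
}

#' @export
print.bootstrap_variance <- function(x, ...) {
  cat(sprintf("Bootstrap (B = %d): estimate %.5g, SE %.5g (%d redrawn)\n",
              x$B, x$point_estimate, x$se_of_estimate, x$n_redrawn))
  invisible(x)
}

# Exact distribution of the signed-rank statistic with (average-rank) ties:
# counts over the support of 2*V, computed by the subset-sum recursion over
# doubled ranks. Equivalent to enumerating all 2^n sign assignments.
signed_rank_counts <- function(ranks2) {
  counts <- numeric(sum(ranks2) + 1)  # index = 2V + 1
  counts[1] <- 1
  for (w in ranks2) {
    shifted <- c(numeric(w), counts[seq_len(length(counts) - w)])
    counts <- counts + shifted
  }
  counts
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about `mu0`, used on estimation biases to test
#' accuracy cell by cell. Zero differences are dropped; tied absolute
#' differences receive average ranks. For `n_effective <= exact_limit` the
#' p-value is exact, from the full distribution of the positive-rank sum over
#' all sign assignments (tie-aware); beyond that a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x Numeric sample.
#' @param mu0 Hypothesised centre (default 0).
#' @param exact_limit Largest `n_effective` for which the exact distribution
#'   is enumerated (default 25).
#' @return An object of class `wilcoxon_result`: list with `statistic` (V,
#'   the positive-rank sum), `n_effective`, `p_value`, `method`, and
#'   `all_zero` flag. When every difference is zero, `V = n(n+1)/4` by
#'   convention and `p = 1`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # V = 6, exact p = 0.25
wilcoxon_signed_rank <- function(x, mu0 = 0, exact_limit = 25) {
  if (length(x) == 0) stop("`x` must be non-empty.", call. = FALSE)
  d <- x - mu0
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    n0 <- length(d)
    return(structure(list(statistic = n0 * (n0 + 1) / 4, n_effective = 0L,
                          p_value = 1, method = "degenerate",
                          all_zero = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= exact_limit) {
    counts <- signed_rank_counts(as.integer(round(2 * r)))
    total <- 2^n
    v2 <- round(2 * v)
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p_ge <- sum(counts[seq.int(v2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - 0.5 * sign(v - mu)) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  structure(list(statistic = v, n_effective = as.integer(n), p_value = p,
                 method = method, all_zero = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %.1f, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}

#' z-test for one slope or the difference of two slopes
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, two-sided p from the standard
#' normal. With the defaults (`b2 = 0`, `se2 = 0`) this reduces to the
#' one-sample test `b1 / se1` used to test fitted slopes against zero.
#'
#' @param b1,se1 First slope and its standard error.
#' @param b2,se2 Second slope and SE (defaults 0: test `b1` against zero).
#' @return List with `z` and `p_value`.
#' @export
slope_z_test <- function(b1, se1, b2 = 0, se2 = 0) {
  if (se1^2 + se2^2 <= 0) {
    stop("At least one standard error must be positive.", call. = FALSE)
  }
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` the family size (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bonferroni_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "bonferroni")
}

#' Simple regression of a covariate on block number
#'
#' Ordinary least squares of `values` on `block_index`, with the t-statistic
#' `b / SE(b)` on `n - 2` degrees of freedom — the control analysis used to
#' check whether fatigue, tiredness or temperature drift across blocks. A
#' perfect fit (zero residual) yields an infinite t, flagged via
#' `perfect_fit`.
#'
#' @param block_index Numeric predictor (block numbers), not all equal.
#' @param values Numeric response, same length, at least 3 points.
#' @return An object of class `block_trend`: list with `slope`, `intercept`,
#'   `slope_se`, `t`, `df`, `p_value`, `r_squared`, `perfect_fit`.
#' @export
block_trend_regression <- function(block_index, values) {
  stopifnot(length(block_index) == length(values), length(values) >= 3)
  if (stats::var(block_index) == 0) {
    stop("`block_index` values are all equal; slope is undefined.",
         call. = FALSE)
  }
  fit <- stats::lm(values ~ block_index)
  sm <- suppressWarnings(summary(fit))  # perfect fits trigger a benign warning
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  df <- length(values) - 2L
  perfect <- rss < 1e-12 * max(1, sum(values^2))
  if (perfect) {
    se <- 0
    zero_b <- abs(b) < 1e-10 * max(1, max(abs(values)))
    t <- if (zero_b) 0 else Inf * sign(b)
    p <- if (zero_b) 1 else 0
    if (zero_b) b <- 0
  } else {
    se <- sm$coefficients[2, 2]
    t <- b / se
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(slope = b, intercept = a, slope_se = se, t = t, df = df,
                 p_value = p, r_squared = sm$r.squared,
                 perfect_fit = perfect),
            class = "block_trend")
}

#' @export
print.block_trend <- function(x, ...) {
  cat(sprintf("Block trend: b = %.4g, t(%d) = %.3g, p = %.4g\n",
              x$slope, x$df, x$t, x$p_value))
  invisible(x)
}
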