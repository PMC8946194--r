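#' Linear fit with optional measurement-error weighting
#'
#' The workhorse behind the binned-bias and RMSE fits. With per-point
#' standard errors `se`, a chi-square (measurement-error) fit is performed:
#' weights `1/se^2`, parameter covariance `(X'WX)^-1` (not rescaled by the
#' residual variance), and `chisq = sum(((y - fit)/se)^2)` serves as the
#' goodness-of-fit statistic on `n - n_params` degrees of freedom. Without
#' `se`, ordinary least squares is used and parameter SEs come from the
#' residual variance (chi-square is then not defined and returned as `NA`).
#' Points with zero or missing `se` are assigned the smallest positive SE in
#' the data, capping their weight.
#'
#' @param x,y Numeric vectors of equal length.
#' @param se Optional per-point standard errors of `y`.
#' @param intercept `TRUE` for the 2-parameter fit `y = a + b x`, `FALSE` for
#'   the 1-parameter through-origin fit `y = b x`.
#' @return An object of class `linear_fit`: list with `slope`, `slope_se`,
#'   `intercept`, `intercept_se` (both `NA` for through-origin fits),
#'   `chisq`, `df`, `n`, `weighted`.
#' @export
#' @examples
#' f <- fit_line(c(1, 2, 3), c(2.1, 3.9, 6.1), se = c(0.1, 0.1, 0.1))
#' f$slope
fit_line <- function(x, y, se = NULL, intercept = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= (1 + intercept) + 1)
  n <- length(x)
  X <- if (intercept) cbind(1, x) else cbind(x)
  p <- ncol(X)
  weighted <- !is.null(se)
  if (weighted) {
    stopifnot(length(se) == n)
    bad <- is.na(se) | se <= 0
    if (all(bad)) stop("All standard errors are zero or missing.",
                       call. = FALSE)
    se[bad] <- min(se[!bad])
    w <- 1 / se^2
  } else {
    w <- rep(1, n)
  }
  XtW <- t(X * w)
  cov_unscaled <- solve(XtW %*% X)
  beta <- unname(drop(cov_unscaled %*% (XtW %*% y)))
  resid <- y - drop(X %*% beta)
  df <- n - p
  if (weighted) {
    chisq <- sum(w * resid^2)
    cov <- cov_unscaled
  } else {
    chisq <- NA_real_
    s2 <- if (df > 0) sum(resid^2) / df else NA_real_
    cov <- s2 * cov_unscaled
  }
  ses <- unname(sqrt(pmax(diag(cov), 0)))
  structure(list(
    slope = beta[p], slope_se = ses[p],
    intercept = if (intercept) beta[1] else NA_real_,
    intercept_se = if (intercept) ses[1] else NA_real_,
    chisq = chisq, df = as.integer(df), n = as.integer(n),
    weighted = weighted
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  if (!is.na(x$intercept)) {
    cat(sprintf("slope = %.4g +/- %.2g, intercept = %.4g +/- %.2g",
                x$slope, x$slope_se, x$intercept, x$intercept_se))
  } else {
    cat(sprintf("through-origin slope = %.4g +/- %.2g", x$slope, x$slope_se))
  }
  if (!is.na(x$chisq)) cat(sprintf(", chi-square(%d) = %.3g", x$df, x$chisq))
  cat("\n")
  invisible(x)
}

fit_to_row <- function(fit) {
  tibble::tibble(slope = fit$slope, slope_se = fit$slope_se,
                 intercept = fit$intercept, intercept_se = fit$intercept_se,
                 chisq = fit$chisq, df = fit$df, n_bins = fit$n)
}

#' Fit binned estimation bias against duration
#'
#' For every (condition, task) in a [make_bins()] series, fits mean bias
#' against bin-centre duration. The default is the weighted 2-parameter fit
#' (weights `1 / se_bias^2`): the intercept is the constant estimation error,
#' the slope the per-second drift of the bias. Each fit's slope is also
#' tested against zero with [slope_z_test()].
#'
#' @param binned A `binned_series` from [make_bins()].
#' @param n_params 2 (intercept + slope, default) or 1 (through origin).
#' @param weighted Use per-bin SEs as chi-square weights (default `TRUE`).
#' @return Tibble with one row per (condition, task): fit parameters, their
#'   SEs, `chisq`, `df`, `n_bins`, `z_vs_zero`, `p_vs_zero`.
#' @export
fit_bias_line <- function(binned, n_params = 2, weighted = TRUE) {
  stopifnot(n_params %in% c(1, 2))
  binned |>
    dplyr::group_by(.data$condition, .data$task) |>
    dplyr::group_modify(function(df, key) {
      se <- if (weighted) df$se_bias
      if (!is.null(se) && all(is.na(se) | se == 0)) se <- NULL  # degenerate
      fit <- fit_line(df$bin_center, df$mean_bias, se = se,
                      intercept = n_params == 2)
      zt <- if (fit$slope_se > 0) slope_z_test(fit$slope, fit$slope_se)
            else list(z = NA_real_, p_value = NA_real_)
      cbind(fit_to_row(fit),
            tibble::tibble(z_vs_zero = zt$z, p_vs_zero = zt$p_value))
    }) |>
    dplyr::ungroup()
}

#' Fit binned RMSE against duration or against the mean estimate
#'
#' Two readings of how estimation uncertainty scales:
#' `mode = "vs_duration"` regresses per-bin RMSE on bin-centre duration with
#' a 2-parameter line (slope and intercept). `mode = "vs_estimate"` regresses
#' per-bin RMSE on the per-bin mean estimate through the origin; under scalar
#' timing RMSE is proportional to the estimate and the through-origin slope
#' *is* the coefficient of variation, returned with its SE (`cv`, `cv_se`).
#' Fits are chi-square weighted when the series carries bootstrap `rmse_se`
#' values, otherwise ordinary least squares.
#'
#' @param binned A `binned_series` from [make_bins()].
#' @param mode `"vs_duration"` or `"vs_estimate"`.
#' @return Tibble with one row per (condition, task). For `"vs_estimate"` the
#'   columns are `cv`, `cv_se`, `chisq`, `df`, `n_bins`.
#' @export
fit_rmse_line <- function(binned, mode = c("vs_duration", "vs_estimate")) {
  mode <- match.arg(mode)
  has_se <- "rmse_se" %in% names(binned) && !all(is.na(binned$rmse_se))
  binned |>
    dplyr::group_by(.data$condition, .data$task) |>
    dplyr::group_modify(function(df, key) {
      se <- if (has_se) df$rmse_se
      if (!is.null(se) && all(is.na(se) | se == 0)) se <- NULL  # degenerate
      if (mode == "vs_duration") {
        fit_to_row(fit_line(df$bin_center, df$rmse, se = se, intercept = TRUE))
      } else {
        fit <- fit_line(df$mean_estimate, df$rmse, se = se, intercept = FALSE)
        tibble::tibble(cv = fit$slope, cv_se = fit$slope_se,
                       chisq = fit$chisq, df = fit$df, n_bins = fit$n)
      }
    }) |>
    dplyr::ungroup()
}

#' Pairwise z-comparisons of fitted slopes
#'
#' Convenience wrapper comparing a column of slopes (with SEs) between all
#' pairs of rows, e.g. CVs across tasks within a condition or bias slopes
#' between motor conditions.
#'
#' @param fits Tibble containing `condition`, `task` and the two columns
#'   named by `slope_col` / `se_col`.
#' @param slope_col,se_col Column names (default `"slope"`, `"slope_se"`).
#' @return Tibble of pairwise comparisons with `z` and `p_value`.
#' @export
compare_slopes <- function(fits, slope_col = "slope", se_col = "slope_se") {
  n <- nrow(fits)
  if (n < 2) return(tibble::tibble())
  pairs <- utils::combn(n, 2)
  lab <- paste(fits$condition, fits$task, sep = "/")
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se1 <- fits[[se_col]][i1]; se2 <- fits[[se_col]][i2]
    zt <- if (isTRUE(se1^2 + se2^2 > 0)) {
      slope_z_test(fits[[slope_col]][i1], se1, fits[[slope_col]][i2], se2)
    } else list(z = NA_real_, p_value = NA_real_)
    tibble::tibble(cell_1 = lab[i1], cell_2 = lab[i2],
                   z = zt$z, p_value = zt$p_value)
  })
  dplyr::bind_rows(out)
}
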