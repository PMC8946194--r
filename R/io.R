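trial_cols_required <- c("participant_id", "condition", "task", "block",
                         "nominal_s", "actual_s", "estimate_s")

#' Write a trial table to CSV
#'
#' Canonical column order: `participant_id, condition, task, block,
#' nominal_s, actual_s, estimate_s[, correct, rt_s]`; any other columns are
#' appended after these.
#'
#' @param trials Trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_cols_required %in% names(trials)))
  opt <- intersect(c("correct", "rt_s"), names(trials))
  rest <- setdiff(names(trials), c(trial_cols_required, opt))
  utils::write.csv(trials[, c(trial_cols_required, opt, rest)], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial CSV
#'
#' Requires the canonical header (`participant_id, condition, task, block,
#' nominal_s, actual_s, estimate_s`); unknown columns are preserved.
#' Validation problems (missing columns, non-numeric or non-positive
#' durations, estimates `<= 0`) are itemised with row numbers before the
#' reader stops.
#'
#' @param path CSV file path.
#' @return A validated trial tibble.
#' @export
ingest_trials <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_cols_required, names(raw))
  if (length(missing) > 0) {
    stop("Missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      more <- if (length(rows) > 5) ", ..." else ""
      problems <<- c(problems,
                     paste0(what, " (row ", shown, more, ")"))
    }
  }
  num_or_na <- function(v) suppressWarnings(as.numeric(v))
  for (col in c("nominal_s", "actual_s", "estimate_s")) {
    v <- num_or_na(raw[[col]])
    note(which(is.na(v) & !is.na(raw[[col]])), paste0("non-numeric ", col))
    raw[[col]] <- v
  }
  note(which(raw$nominal_s <= 0), "nominal_s must be positive")
  note(which(raw$actual_s <= 0), "actual_s must be positive")
  note(which(raw$estimate_s <= 0), "estimate_s must be positive")
  note(which(is.na(raw$estimate_s)), "missing estimate_s")
  if (length(problems) > 0) {
    stop("Invalid trial file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Write covariate records to CSV
#'
#' @param covariates Covariate tibble from [generate_covariates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' Reference cell means of the 16-participant dual-task study
#'
#' Published group-mean verbal duration estimates (seconds, with standard
#' errors across participants) for every motor condition x cognitive task x
#' nominal interval cell of the reference 2 x 4 x 5 experiment. These are the
#' summary values against which the package's deterministic analyses (bias
#' slopes from per-interval means, percentual motor/cognitive effects) are
#' checked.
#'
#' @return Tibble with columns `condition`, `task`, `nominal_s`,
#'   `mean_estimate`, `se_estimate`.
#' @export
reference_cell_means <- function() {
  path <- system.file("extdata", "reference_cell_means.csv",
                      package = "prospectime", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
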