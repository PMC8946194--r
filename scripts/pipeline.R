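#!/usr/bin/env Rscript
# Thin command-line wrapper over the prospectime pipeline.
#
#   Rscript scripts/pipeline.R simulate [--config cfg.json] [--seed N]
#                              [--model linear|pacemaker] --out <dir>
#   Rscript scripts/pipeline.R analyze --in trials.csv [--filter-k 3]
#                              [--bin-width 2] [--seed N] --out <dir>
#
# Exit codes: 0 ok, 1 validation error, 2 runtime error.

suppressPackageStartupMessages(library(prospectime))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: pipeline.R {simulate|analyze} [options] --out <dir>\n")
  quit(status = 1)
}
if (length(args) < 1) usage()
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
}

out_dir <- get_opt("--out")
if (is.null(out_dir)) usage()

status <- tryCatch({
  cfg_path <- get_opt("--config")
  cfg <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path)
         else pipeline_config()
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (cmd == "simulate") {
    model <- get_opt("--model")
    if (!is.null(model)) cfg$model <- match.arg(model,
                                                c("linear", "pacemaker"))
  } else if (cmd == "analyze") {
    input <- get_opt("--in")
    if (is.null(input)) usage()
    cfg$input_csv <- input
    fk <- get_opt("--filter-k"); if (!is.null(fk)) cfg$filter_k <- as.numeric(fk)
    bw <- get_opt("--bin-width"); if (!is.null(bw)) cfg$bin_width <- as.numeric(bw)
  } else usage()
  report <- suppressMessages(run_pipeline(cfg, out_dir = out_dir))
  print(report)
  0L
}, error = function(e) {
  message("Error: ", conditionMessage(e))
  if (grepl("Invalid trial file|Missing required|File not found|must ",
            conditionMessage(e))) 1L else 2L
})
quit(status = status)
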