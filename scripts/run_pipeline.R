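#!/usr/bin/env Rscript
# Command-line front end over the impactwave pipeline.
#
#   Rscript scripts/run_pipeline.R run      --out DIR [--config FILE] [--seed N]
#   Rscript scripts/run_pipeline.R generate --out DIR [--config FILE] [--seed N]
#   Rscript scripts/run_pipeline.R analyze  --out DIR --signals DIR [--config FILE]
#   Rscript scripts/run_pipeline.R stats    --out DIR --results FILE
#
# `run` executes generate + analyze + stats; `generate` stops after writing
# the signal CSVs; `analyze` starts from an existing signal directory;
# `stats` re-runs the statistics stage on an existing results.csv.
# --config is a JSON file of run_config() fields; flags override it.

suppressPackageStartupMessages(library(impactwave))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("run", "generate", "analyze", "stats")) {
  message("usage: run_pipeline.R {run|generate|analyze|stats} --out DIR ",
          "[--config FILE] [--seed N] [--signals DIR] [--results FILE]")
  quit(status = 2)
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1]
}

out_dir <- get_arg("--out")
if (is.null(out_dir)) { message("error: --out is required"); quit(status = 2) }

status <- tryCatch({
  if (cmd == "stats") {
    results_file <- get_arg("--results",
                            file.path(out_dir, "results.csv"))
    tbl <- utils::read.csv(results_file, stringsAsFactors = FALSE)
    class(tbl) <- c("factorial_result", "data.frame")
    dir.create(file.path(out_dir, "stats"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(factor_test_matrix(tbl),
                     file.path(out_dir, "stats", "factor_tests.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(fit_indicators(tbl),
                     file.path(out_dir, "stats", "fit_summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    message("stats written under ", file.path(out_dir, "stats"))
  } else {
    cfg_file <- get_arg("--config")
    cfg <- if (!is.null(cfg_file)) {
      read_run_config(cfg_file, output_dir = out_dir)
    } else {
      run_config(output_dir = out_dir)
    }
    seed <- get_arg("--seed")
    if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
    if (cmd == "generate") {
      scens <- generate_matrix(positions = cfg$positions,
                               materials = cfg$materials,
                               velocities = cfg$velocities,
                               sizes = cfg$sizes, fs = cfg$fs,
                               duration = cfg$duration, snr_db = cfg$snr_db,
                               master_seed = cfg$master_seed)
      sig_dir <- file.path(out_dir, "signals")
      dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
      for (sc in scens)
        write_signal(simulate_impact(sc, cfg$head),
                     file.path(sig_dir, paste0(sc$scenario_id, ".csv")))
      message(length(scens), " signals written under ", sig_dir)
    } else {
      run_pipeline(cfg, signals_dir = get_arg("--signals"))
      message("run complete: ", out_dir)
    }
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
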