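#!/usr/bin/env Rscript
# Thin shell wrapper over radiostage::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R --out-dir DIR [--config config.yaml]
#                                  [--seed INT]

suppressPackageStartupMessages(library(radiostage))

args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}

cfg_path <- getopt("--config")
cfg <- if (is.null(cfg_path)) pipeline_config()
       else read_pipeline_config(cfg_path)
out_dir <- getopt("--out-dir")
if (!is.null(out_dir)) cfg$out_dir <- out_dir
seed <- getopt("--seed")
if (!is.null(seed)) cfg$study$seed <- as.integer(seed)

res <- run_pipeline(cfg)
cat(sprintf("pipeline complete: %d subjects, %d selected features, %d hubs\n",
            nrow(res$study$clinical), length(res$selection$selected),
            length(res$grn$hubs)))
cat(sprintf("artifacts written to %s\n", cfg$out_dir))
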