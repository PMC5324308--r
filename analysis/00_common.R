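# Shared preamble for the analysis drivers: one master seed, one
# default configuration, outputs under results/.
suppressPackageStartupMessages(library(islandrep))

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
CFG <- default_config(seed = SEED)
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
res_path <- function(...) file.path(RESULTS, ...)
tsv <- function(df, f) {
  utils::write.table(df, res_path(f), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("  wrote", res_path(f), "\n")
}
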