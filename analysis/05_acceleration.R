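#!/usr/bin/env Rscript
# The accelerated-differentiation ordering statistic: fraction of
# control-upregulated genes whose knockdown EB value lags strictly
# between ES and control EB, with bootstrap errors and the per-sample
# shuffle null, over an alpha grid and both EB stages.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

data <- simulate_dataset(CFG)
rpkm <- compute_rpkm(data$em)
res <- do.call(rbind, lapply(c("EB_d6", "EB_d10"), function(stage)
  accelerated_differentiation(rpkm, data$design, stage,
                              alphas = CFG$accel$alphas,
                              n_boot = CFG$accel$n_boot,
                              n_shuffles = CFG$accel$n_shuffles,
                              seed = SEED + 4000)))
tsv(res, "acceleration.tsv")
print(res[, c("stage", "alpha", "n_genes", "observed_fraction",
              "expected_mean", "z_score", "verdict")], digits = 3)
cat("\nNote: with correlated real-data structure the observed fraction\n")
cat("sits above the gene-exchangeable shuffle expectation; planted\n")
cat("acceleration shifts it back down (see the methods vignette).\n")
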