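#!/usr/bin/env Rscript
# Generate the synthetic study: toy genome, repeat annotation with a
# planted hierarchy, ChIP/Input/RNA tracks with planted enrichment,
# attenuation and de-repression, and the differentiation time course.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

CFG$outdir <- res_path("dataset")
data <- simulate_dataset(CFG)
cat(sprintf("Simulated %d-chromosome genome (%.1f Mb), %d planted islands,\n",
            length(GenomeInfoDb::seqnames(data$genome)),
            genome_size(data$genome) / 1e6,
            length(data$planted_islands)))
cat(sprintf("%d repeat elements in %d subfamilies, %d genes x %d samples,\n",
            length(data$repeats),
            length(unique(S4Vectors::mcols(data$repeats)$repeat_name)),
            nrow(data$em$counts), ncol(data$em$counts)))
cat(sprintf("ChIP tracks: %d/%d/%d reads (ctrl/kd/input); RNA: %d/%d.\n",
            n_reads(data$chip_ctrl), n_reads(data$chip_kd),
            n_reads(data$input), n_reads(data$rna_ctrl),
            n_reads(data$rna_kd)))
cat("Inputs and truth tables under", CFG$outdir, "\n")
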