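#!/usr/bin/env Rscript
# Relate LTR/ERV elements to genes: elements within 10 kb of a TSS,
# genic context (exonic/intronic/intergenic), and the expression of
# elements near upregulated versus unchanged genes.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

data <- simulate_dataset(CFG)
elements <- data$repeats[
  S4Vectors::mcols(data$repeats)$repeat_class == "LTR"]
rec <- elements_near_tss(elements, data$models, CFG$proximity$window_bp)
tsv(rec, "proximity_records.tsv")
cat("Genic context of LTR elements near TSSs:\n")
print(table(rec$context))
de <- detect_de_genes(data$em, "kd_ESC", "ctrl_ESC")
fc <- islandrep:::element_fold_change(data$rna_ctrl, data$rna_kd,
                                      elements)
rep_out <- proximity_expression_report(rec, de, fc)
tsv(rep_out$per_gene, "proximity_per_gene.tsv")
cat(sprintf("\n%d upregulated genes; element fold-changes near them vs near\n",
            rep_out$n_upregulated))
cat(sprintf("unchanged genes: KS D = %.3f, p = %.2g (%s).\n",
            rep_out$ks$ks_statistic, rep_out$ks$ks_p_value,
            rep_out$ks$direction))
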