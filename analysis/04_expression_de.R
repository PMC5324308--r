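#!/usr/bin/env Rscript
# RPKM quantification, knockdown-vs-control DE genes (FC > 2,
# FDR < 0.001, RPKM >= 3 in at least one condition), k-means patterns
# and sample PCA for the differentiation time course.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

data <- simulate_dataset(CFG)
rpkm <- compute_rpkm(data$em)
de <- detect_de_genes(data$em, "kd_ESC", "ctrl_ESC")
tsv(de, "de_genes.tsv")
strong <- names(data$truth$expression$de_log2fc)[
  abs(data$truth$expression$de_log2fc) >= 2]
cat(sprintf("%d of %d tested genes DE (%d genes excluded by the RPKM floor).\n",
            sum(de$is_de), nrow(de), attr(de, "n_excluded")))
cat(sprintf("Planted >=4-fold genes recovered: %.0f%%.\n",
            100 * mean(strong %in% de$gene_id[de$is_de])))
pca <- pca_time_course(rpkm, data$design)
tsv(pca, "pca.tsv")
print(pca, digits = 3)
de_ids <- de$gene_id[de$is_de]
km <- kmeans_time_course(rpkm[de_ids, , drop = FALSE],
                         k = min(20, max(2, length(de_ids) %/% 10)),
                         seed = SEED + 3000)
tsv(data.frame(gene_id = names(km$cluster), cluster = unname(km$cluster)),
    "kmeans_clusters.tsv")
cat(sprintf("k-means: %d DE genes in %d clusters.\n",
            length(km$cluster), km$k))
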