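# islandrep

Analysis pipeline for heterochromatin ChIP-Seq and differentiation
RNA-Seq studies of the kind that ask: *which broad histone-mark domains
depend on a silencing factor, which repeat elements live inside them,
and what happens to those elements — and to differentiation — when the
factor is knocked down?* The package implements the complete chain of
computations for such a study and ships a deterministic synthetic-data
generator with known ground truth, so every stage is testable end to
end without any external sequencing data.

## Who it is for

Computational biologists analysing broad repressive marks (H4K20me3,
H3K9me3) and retroelement silencing in ES-cell knockdown experiments,
or anyone who needs a transparent, fully tested reference
implementation of the statistics below on BED/TSV-scale inputs.

## What it computes

**Broad-island calling (SICER-style).** Each chromosome is tiled into
windows of *w* = 200 bp; a window with read count *k* is eligible when
its Poisson upper-tail probability under the genome-wide background
rate λ (reads per window) satisfies P(X ≥ k) ≤ 0.2; eligible windows
separated by at most *g* = 400 bp are clustered into islands; each
island is then tested by a Poisson comparison of its ChIP count
against the library-scaled Input count, with Benjamini–Hochberg
control at FDR 0.001 across islands.

**Island density and differential islands.** Density is RPBM — reads
per base per million mapped reads:
`count / length / (library_size / 10^6)`. Two conditions are compared
at fixed islands by a two-sided binomial test of the condition-A count
out of the pooled count against the library-size-ratio null, with BH
correction; calls use fold-change ≥ 1.5 and FDR ≤ 0.001.

**Repeat enrichment against a matched null.** Per-island percent
coverage by a repeat class/family/subfamily is compared with the same
quantity over matched random regions (equal count, identical lengths,
same chromosome, uniform placement) by the two-sample
Kolmogorov–Smirnov statistic D = sup |F_obs − F_null|, with the
asymptotic two-sided p-value; a subfamily × island-set matrix of
observed/expected overlap ratios summarises enrichment.

**Expression.** RPKM (`count / (length/10^3) / (library/10^6)`), DE
genes by the pooled-count binomial test (FC > 2, FDR < 0.001, genes
with RPKM < 3 in both conditions excluded), k-means patterns and
sample PCA on log2(RPKM + 1), retroelement expression as aggregate
RPBM per subfamily with knockdown/control fold-changes, and a strict
`> 0.003` RPBM filter for expressed elements.

**Accelerated-differentiation ordering statistic.** For genes
upregulated at least α-fold from the ES state to the control EB stage,
the observed quantity is the fraction whose knockdown EB value lies
strictly between the ES and control EB values (they "lag behind"):
EB(ctrl) > EB(kd) > ESC. Error bars come from bootstrapping genes; the
chance expectation comes from independently permuting the three
expression vectors over all genes, re-applying the α selection, and
recomputing the fraction; the verdict compares observed and expected
at |z| ≥ 2 with a smoothed two-sided empirical p.

**Proximity.** LTR/ERV elements within 10 kb of a gene's TSS (signed,
strand-aware distances), exonic ≻ intronic ≻ intergenic context, and a
KS comparison of element expression fold-changes near upregulated
versus unchanged genes.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default synthetic dataset (3 × 2 Mb genome, 60 planted 2.5-kb islands,
20 repeat subfamilies, 5000 genes; everything seeded):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_call_islands.R --seed 1
Rscript analysis/06_retroelement_expression.R --seed 1
```

prints, among other things:

```
Called 60 islands; 30 decreased / 0 increased in the knockdown.
Planted 2.5x attenuation recovered at 100% sensitivity.
Median island log2 fold-change (kd/ctrl): -0.59.
...
Spearman rank correlation with planted folds: 0.994
```

Half the planted islands carry a 2.5× knockdown attenuation, and
exactly those 30 come back as "decreased"; the planted de-repression
fold ladder over the 20 repeat subfamilies is recovered in rank order
(ρ = 0.994). Tables land under `results/`. The same computations are
available directly:

```r
library(islandrep)
data <- simulate_dataset(default_config(seed = 1))
islands <- call_islands(data$chip_ctrl, data$input)   # w=200, g=400, FDR 1e-3
diff <- differential_islands(islands, data$chip_ctrl, data$chip_kd)
table(S4Vectors::mcols(diff)$call)
```

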