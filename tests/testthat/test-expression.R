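small_em <- function(counts, lengths) {
  expression_matrix(counts, lengths)
}

test_that("RPKM follows the definition and a hand-computed oracle", {
  m <- matrix(c(100, 0, 50, 200, 10, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # single-gene check: 100 reads, 2000 bp, library 1e6 -> 50
  m1 <- matrix(c(100, 1e6 - 100), nrow = 2,
               dimnames = list(c("g1", "gfill"), "s1"))
  em1 <- small_em(m1, c(g1 = 2000, gfill = 1000))
  expect_equal(compute_rpkm(em1)["g1", "s1"], 100 / 2 / 1)
  # full 3x2 oracle recomputation
  em <- small_em(m, c(g1 = 1000, g2 = 2000, g3 = 500))
  r <- compute_rpkm(em)
  lib <- colSums(m)
  for (i in 1:3) for (j in 1:2)
    expect_equal(r[i, j], m[i, j] / (c(1000, 2000, 500)[i] / 1e3) /
                   (unname(lib[j]) / 1e6))
  expect_equal(r["g2", "s1"], 0)
  # zero library errors
  mz <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(compute_rpkm(small_em(mz, c(a = 100, b = 100))), "library")
})

test_that("DE detection applies the RPKM floor and the binomial oracle", {
  n <- 200
  counts <- matrix(5000, n, 2,
                   dimnames = list(sprintf("g%03d", 1:n), c("A", "B")))
  lengths <- setNames(rep(2000, n), rownames(counts))
  # one strongly changed gene: 400 vs 100
  counts["g001", ] <- c(400, 100)
  # one gene below the floor in both groups
  counts["g002", ] <- c(1, 1)
  em <- small_em(counts, lengths)
  de <- detect_de_genes(em, "A", "B")
  expect_false("g002" %in% de$gene_id)          # excluded before testing
  expect_equal(attr(de, "n_excluded"), 1L)
  row1 <- de[de$gene_id == "g001", ]
  libA <- sum(counts[, "A"])
  libB <- sum(counts[, "B"])
  p0 <- libA / (libA + libB)
  p_oracle <- min(1, 2 * min(pbinom(400, 500, p0),
                             pbinom(399, 500, p0, lower.tail = FALSE)))
  expect_equal(row1$p_value, p_oracle)
  expect_true(row1$is_de)
  expect_gt(row1$log2_fold_change, 1)
  # equal counts with equal libraries are never DE
  expect_true(all(!de$is_de[de$gene_id != "g001"]))
})

test_that("binomial DE test is calibrated under Poisson noise", {
  # identical Poisson rates in both groups: the conditional count split
  # is exactly binomial, so q <= 0.001 calls should be rare
  calls <- vapply(1:5, function(s) {
    set.seed(800 + s)
    mu <- rlnorm(3000, 5, 1)
    counts <- cbind(A = rpois(3000, mu), B = rpois(3000, mu))
    rownames(counts) <- sprintf("g%04d", 1:3000)
    em <- small_em(counts, setNames(rep(1000, 3000), rownames(counts)))
    sum(detect_de_genes(em, "A", "B")$is_de)
  }, 0L)
  expect_gte(sum(calls <= 5), 4)
})

test_that("planted DE genes in the time course are recovered", {
  tc <- generate_expression_timecourse(n_genes = 3000, seed = 41)
  de <- detect_de_genes(tc$em, "kd_ESC", "ctrl_ESC")
  called <- de$gene_id[de$is_de]
  # sensitivity assessed at four-fold and stronger planted effects;
  # two-fold genes sit at the FC threshold under count noise
  strong <- names(tc$truth$de_log2fc)[abs(tc$truth$de_log2fc) >= 2]
  expect_gte(mean(strong %in% called), 0.9)
})

test_that("k-means recovers two planted expression patterns", {
  set.seed(19)
  up <- matrix(rep(c(1, 5, 25), each = 40), 40) +
    matrix(rnorm(120, sd = 0.05), 40)
  down <- matrix(rep(c(25, 5, 1), each = 40), 40) +
    matrix(rnorm(120, sd = 0.05), 40)
  rpkm <- rbind(up, down)
  rownames(rpkm) <- sprintf("g%02d", 1:80)
  colnames(rpkm) <- c("s1", "s2", "s3")
  km <- kmeans_time_course(rpkm, k = 2, seed = 31)
  truth <- rep(1:2, each = 40)
  tab <- table(km$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 80)  # pure clusters
  # determinism and the k = 1 edge case
  km2 <- kmeans_time_course(rpkm, k = 2, seed = 31)
  expect_identical(km$cluster, km2$cluster)
  expect_true(all(kmeans_time_course(rpkm, k = 1, seed = 1)$cluster == 1))
  expect_error(kmeans_time_course(rpkm, k = 0), "k must be")
})

test_that("PCA separates sample types with the ES anchor convention", {
  tc <- generate_expression_timecourse(n_genes = 1000, seed = 53)
  rpkm <- compute_rpkm(tc$em)
  pc <- pca_time_course(rpkm, tc$design)
  expect_equal(nrow(pc), 6)
  # sign convention: the control ES sample has negative PC1
  expect_lt(pc$PC1[pc$sample_id == "ctrl_ESC"], 0)
  # stages separate along PC1 more than genotypes do
  byst <- tapply(pc$PC1, pc$stage, mean)
  expect_gt(max(byst) - min(byst), 1e-6)
  # duplicated samples get identical coordinates
  cn <- c("ctrl_ESC", "ctrl_EB_d6", "ctrl_EB_d10", "ctrl_ESC")
  r2 <- rpkm[, c(1, 2, 3, 1)]
  colnames(r2) <- c(cn[1:3], "dup_ESC")
  d2 <- data.frame(sample_id = colnames(r2),
                   genotype = "control",
                   stage = c("ESC", "EB_d6", "EB_d10", "ESC"))
  pc2 <- pca_time_course(r2, d2)
  expect_equal(pc2$PC1[1], pc2$PC1[4], tolerance = 1e-9)
  expect_equal(pc2$PC2[1], pc2$PC2[4], tolerance = 1e-9)
})

test_that("repeat expression aggregates match a linear-scan oracle", {
  g <- make_genome("chr1", 1e5)
  gr <- GRanges("chr1", IRanges::IRanges(c(1001, 5001, 20001),
                                         width = c(1000, 1000, 2000)))
  GenomeInfoDb::seqinfo(gr) <- g
  ann <- repeat_annotation(gr, c("LINE", "LINE", "LTR"),
                           c("L1", "L1", "ERVK"),
                           c("L1A", "L1A", "IAP"))
  set.seed(61)
  pos <- sort(sample.int(1e5, 5000) - 1)
  tr <- read_track(list(chr1 = pos), g, read_length = 1)
  rex <- repeat_expression(tr, ann)
  agg <- rex$aggregates
  l1 <- agg[agg$level == "name" & agg$key == "L1A", ]
  want <- sum(pos >= 1000 & pos < 2000) + sum(pos >= 5000 & pos < 6000)
  expect_equal(l1$count, want)
  expect_equal(l1$density, want / 2000 / (5000 / 1e6))
  # empty track gives all-zero densities
  tr0 <- read_track(list(chr1 = numeric(0)), g, read_length = 1,
                    library_size = 10)
  expect_true(all(repeat_expression(tr0, ann)$aggregates$density == 0))
})

test_that("uniform reads give near-equal aggregate densities per label", {
  g <- make_genome("chr1", 1e6)
  cfg <- data.frame(name = c("a_syn", "b_syn"), family = c("L1", "ERVK"),
                    class = c("LINE", "LTR"), count = c(50, 50),
                    length = c(500, 500), co_placement = 0)
  ann <- generate_repeat_annotation(g, cfg, seed = 71)
  set.seed(72)
  tr <- read_track(list(chr1 = sort(floor(runif(2e5, 0, 1e6)))), g,
                   read_length = 1)
  agg <- repeat_expression(tr, ann)$aggregates
  d <- agg$density[agg$level == "name"]
  expect_lt(abs(d[1] / d[2] - 1), 0.2)
})

test_that("the expressed-element filter is strictly greater-than", {
  g <- make_genome("chr1", 1e5)
  gr <- GRanges("chr1", IRanges::IRanges(c(1, 1001), width = 1000))
  GenomeInfoDb::seqinfo(gr) <- g
  ann <- repeat_annotation(gr, c("LTR", "LTR"), c("ERVK", "ERVK"),
                           c("A", "B"))
  S4Vectors::mcols(ann)$rpbm <- c(0.003, 0.0031)
  kept <- filter_expressed_repeats(ann, 0.003)
  expect_length(kept, 1)
  expect_equal(S4Vectors::mcols(kept)$repeat_name, "B")
  S4Vectors::mcols(ann)$rpbm <- c(0, 0)
  expect_length(filter_expressed_repeats(ann, 0.003), 0)
})

test_that("subfamily fold-changes are reciprocal and recover planting", {
  g <- make_genome("chr1", 2e6)
  # the planted subfamily is a small fraction of annotated bp, so the
  # library-size shift from its de-repression stays modest
  cfg <- data.frame(name = c("hot_syn", "cold1_syn", "cold2_syn"),
                    family = c("ERVK", "L1", "L1"),
                    class = c("LTR", "LINE", "LINE"),
                    count = c(5, 200, 200), length = c(200, 800, 800),
                    co_placement = 0)
  ann <- generate_repeat_annotation(g, cfg, seed = 81)
  rna <- generate_rna_repeat_reads(g, ann, c(hot_syn = 50), depth = 2e5,
                                   seed = 82)
  fc <- repeat_subfamily_fold_change(rna$rna_ctrl, rna$rna_kd, ann)
  expect_equal(fc$key[1], "hot_syn")
  expect_true(fc$fold_change[1] >= 35 && fc$fold_change[1] <= 65)
  # identical tracks: all fold-changes exactly 1
  fc1 <- repeat_subfamily_fold_change(rna$rna_ctrl, rna$rna_ctrl, ann)
  expect_true(all(fc1$fold_change == 1))
  # swapping tracks inverts every fold-change exactly
  fcs <- repeat_subfamily_fold_change(rna$rna_kd, rna$rna_ctrl, ann)
  m <- merge(fc, fcs, by = "key")
  expect_equal(m$fold_change.x * m$fold_change.y, rep(1, nrow(m)),
               tolerance = 1e-12)
})

test_that("counts and design TSVs round-trip through their readers", {
  tc <- generate_expression_timecourse(n_genes = 50, seed = 91)
  f <- withr::local_tempfile()
  write_counts_tsv(tc$em, f)
  back <- read_counts_tsv(f)
  expect_equal(back$counts, tc$em$counts)
  expect_equal(back$lengths, tc$em$lengths)
  fd <- withr::local_tempfile()
  write_tsv(tc$design, fd)
  expect_equal(read_design_tsv(fd), tc$design)
})
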