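# Gene-level expression quantification (RPKM), differential expression
# between conditions, time-course clustering/PCA plumbing, and
# repeat-element expression from RNA read tracks.

#' Construct a gene x sample expression count matrix
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param lengths Exon-model length in bp per gene (named or in row
#'   order), all positive.
#' @return Object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    stop("one exon-model length per gene required")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("exon-model lengths must be positive")
  names(lengths) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Read a count matrix from TSV (gene_id, length, one column per sample)
#' @param path TSV file with header.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 3) stop("counts TSV needs gene_id, length and >=1 sample")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, stats::setNames(df[[2]], df[[1]]))
}

#' Write a count matrix to TSV
#' @param em An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$counts),
                   length = unname(em$lengths),
                   em$counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a sample design table (sample_id, genotype, stage)
#' @param path TSV file with header.
#' @export
read_design_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "genotype", "stage")
  if (!all(need %in% names(df)))
    stop("design TSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' RPKM expression values
#'
#' RPKM (reads per kilobase of exon model per million mapped reads):
#' `count / (length / 1e3) / (column_sum / 1e6)`.
#'
#' @param em An `ExpressionMatrix`.
#' @return Numeric gene x sample matrix of RPKM values.
#' @export
compute_rpkm <- function(em) {
  lib <- colSums(em$counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(em$counts)[lib <= 0], collapse = ", "))
  sweep(em$counts / (em$lengths / 1e3), 2, lib / 1e6, "/")
}

#' Detect differentially expressed genes between two sample groups
#'
#' Counts are pooled within each group and compared per gene by a
#' two-sided binomial test of the group-A count out of the pooled total
#' against the library-size-ratio null, with BH correction across the
#' tested genes. Genes whose pooled RPKM falls below `rpkm_min` in both
#' groups are excluded before testing. `log2_fold_change` is
#' `log2((rpkm_A + eps)/(rpkm_B + eps))`.
#'
#' @param em An `ExpressionMatrix`.
#' @param samples_A,samples_B Non-empty character vectors of sample ids.
#' @param fc Fold-change threshold for calling a gene DE (default 2).
#' @param fdr BH q-value threshold (default 0.001).
#' @param rpkm_min RPKM floor; genes below it in both groups are
#'   excluded (default 3).
#' @param pseudocount RPKM pseudocount in the fold-change (default 0.1).
#' @return data.frame of tested genes: `gene_id`, `count_A`, `count_B`,
#'   `rpkm_A`, `rpkm_B`, `log2_fold_change`, `p_value`, `q_value`,
#'   `is_de`. The number of floor-excluded genes is in attribute
#'   `n_excluded`.
#' @export
detect_de_genes <- function(em, samples_A, samples_B, fc = 2, fdr = 0.001,
                            rpkm_min = 3, pseudocount = 0.1) {
  if (length(samples_A) == 0 || length(samples_B) == 0)
    stop("both sample groups must be non-empty")
  missing <- setdiff(c(samples_A, samples_B), colnames(em$counts))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "))
  a <- rowSums(em$counts[, samples_A, drop = FALSE])
  b <- rowSums(em$counts[, samples_B, drop = FALSE])
  la <- sum(a)
  lb <- sum(b)
  if (la <= 0 || lb <= 0) stop("zero pooled library size in a group")
  rpkm_a <- a / (em$lengths / 1e3) / (la / 1e6)
  rpkm_b <- b / (em$lengths / 1e3) / (lb / 1e6)
  keep <- rpkm_a >= rpkm_min | rpkm_b >= rpkm_min
  out <- data.frame(gene_id = rownames(em$counts), count_A = a,
                    count_B = b, rpkm_A = rpkm_a, rpkm_B = rpkm_b,
                    row.names = NULL)[keep, , drop = FALSE]
  out$log2_fold_change <- log2((out$rpkm_A + pseudocount) /
                                 (out$rpkm_B + pseudocount))
  out$p_value <- binom_p_two_sided(out$count_A, out$count_A + out$count_B,
                                   la / (la + lb))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$is_de <- out$q_value <= fdr & abs(out$log2_fold_change) >= log2(fc)
  attr(out, "n_excluded") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' K-means clustering of time-course expression patterns
#'
#' Rows (genes) of `log2(RPKM + 1)` are z-scored, then clustered with
#' [stats::kmeans] under a fixed seed. Genes with zero variance across
#' samples get a zero z-score profile.
#'
#' @param rpkm RPKM matrix (genes x samples), typically restricted to
#'   DE genes.
#' @param k Number of clusters (default 20).
#' @param seed Integer seed.
#' @return List with `cluster` (named labels), `centers` (k x sample
#'   centroid matrix) and `k`.
#' @export
kmeans_time_course <- function(rpkm, k = 20L, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(rpkm) < k) stop("need at least k genes")
  x <- log2(rpkm + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  fit <- with_seed(seed,
                   stats::kmeans(z, centers = k, nstart = 10, iter.max = 100))
  list(cluster = stats::setNames(fit$cluster, rownames(rpkm)),
       centers = fit$centers, k = k)
}

#' PCA of samples on log2(RPKM + 1)
#'
#' Centered (unscaled) PCA of the samples. The sign of PC1 is fixed so
#' that the first control sample of the first stage (the undifferentiated
#' ES state) has negative PC1.
#'
#' @param rpkm RPKM matrix (genes x samples).
#' @param design Design data.frame (`sample_id`, `genotype`, `stage`).
#' @return data.frame of `sample_id`, `genotype`, `stage`, `PC1`, `PC2`;
#'   attribute `var_explained` carries per-component variance fractions.
#' @export
pca_time_course <- function(rpkm, design) {
  if (ncol(rpkm) < 3) stop("need at least 3 samples for PCA")
  x <- t(log2(rpkm + 1))
  if (all(apply(x, 2, stats::sd) == 0)) stop("constant expression matrix")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  sc <- fit$x
  design <- design[match(rownames(sc), design$sample_id), ]
  anchor <- which(design$genotype == "control" &
                    design$stage == design$stage[which.min(
                      match(design$stage, unique(design$stage)))])[1]
  if (!is.na(anchor) && sc[anchor, 1] > 0) sc[, 1] <- -sc[, 1]
  out <- data.frame(sample_id = rownames(sc),
                    genotype = design$genotype, stage = design$stage,
                    PC1 = sc[, 1], PC2 = sc[, 2], row.names = NULL)
  attr(out, "var_explained") <- fit$sdev^2 / sum(fit$sdev^2)
  out
}

#' Repeat-element expression densities from an RNA read track
#'
#' Per-element RPBM, plus aggregate densities per label at each
#' hierarchy level: reads falling in the union of the label's elements
#' divided by the union's total bp and the per-million library factor.
#'
#' @param rna_track `ReadTrack` of RNA-seq reads.
#' @param repeats Repeat annotation `GRanges`.
#' @return List with `elements` (the annotation with an added `rpbm`
#'   column) and `aggregates` (data.frame: `level`, `key`,
#'   `n_elements`, `total_bp`, `count`, `density`).
#' @export
repeat_expression <- function(rna_track, repeats) {
  if (length(repeats) == 0) stop("repeat annotation is empty")
  elements <- repeats
  S4Vectors::mcols(elements)$rpbm <- compute_rpbm(rna_track, repeats)
  rows <- list()
  for (level in REPEAT_LEVELS) {
    labels <- S4Vectors::mcols(repeats)[[paste0("repeat_", level)]]
    for (key in sort(unique(labels))) {
      u <- GenomicRanges::reduce(repeats[labels == key],
                                 ignore.strand = TRUE)
      bp <- sum(BiocGenerics::width(u))
      cnt <- sum(count_reads(rna_track, u))
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, key = key, n_elements = sum(labels == key),
        total_bp = bp, count = cnt,
        density = cnt / bp / (rna_track$library_size / 1e6))
    }
  }
  list(elements = elements, aggregates = do.call(rbind, rows))
}

#' Filter repeat elements by expression density
#'
#' Keeps elements whose RPBM strictly exceeds the threshold (the
#' "expressed" subset; default > 0.003 RPBM per site).
#'
#' @param elements `GRanges` with an `rpbm` metadata column (as
#'   returned in `repeat_expression()$elements`).
#' @param threshold Strict lower bound on RPBM (default 0.003).
#' @export
filter_expressed_repeats <- function(elements, threshold = 0.003) {
  rpbm <- S4Vectors::mcols(elements)$rpbm
  if (is.null(rpbm)) stop("elements must carry an 'rpbm' column")
  elements[rpbm > threshold]
}

#' Expression fold-change of repeat labels between two RNA tracks
#'
#' Per label, aggregate RPBM density in each track with a half-read
#' pseudocount over the label's total bp; fold-change is condition B
#' over condition A (e.g. knockdown over control), so values > 1 mean
#' de-repression in B. Swapping the tracks inverts every fold-change.
#'
#' @param track_A,track_B `ReadTrack` objects (control, knockdown).
#' @param repeats Repeat annotation `GRanges`.
#' @param level Hierarchy level (default `"name"`).
#' @return data.frame of `key`, `n_elements`, `total_bp`, `density_A`,
#'   `density_B`, `fold_change`, sorted by descending fold-change.
#' @export
repeat_subfamily_fold_change <- function(track_A, track_B, repeats,
                                         level = "name") {
  level <- match.arg(level, REPEAT_LEVELS)
  labels <- S4Vectors::mcols(repeats)[[paste0("repeat_", level)]]
  keys <- sort(unique(labels))
  rows <- lapply(keys, function(key) {
    u <- GenomicRanges::reduce(repeats[labels == key], ignore.strand = TRUE)
    bp <- sum(BiocGenerics::width(u))
    ca <- sum(count_reads(track_A, u))
    cb <- sum(count_reads(track_B, u))
    da <- ca / bp / (track_A$library_size / 1e6)
    db <- cb / bp / (track_B$library_size / 1e6)
    ea <- 0.5 / bp / (track_A$library_size / 1e6)
    eb <- 0.5 / bp / (track_B$library_size / 1e6)
    data.frame(key = key, n_elements = sum(labels == key), total_bp = bp,
               density_A = da, density_B = db,
               fold_change = (db + eb) / (da + ea))
  })
  out <- do.call(rbind, rows)
  out[order(-out$fold_change, out$key), , drop = FALSE]
}
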