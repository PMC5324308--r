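# Broad-island identification and between-condition comparison.
#
# The caller follows the SICER window/gap design: fixed non-overlapping
# windows are scored against a genome-wide Poisson background, runs of
# eligible windows separated by at most `gap_bp` are clustered into
# islands, and each island is then tested against the library-scaled
# Input track with Benjamini-Hochberg control across islands.

#' Call read-enriched islands relative to an Input track
#'
#' @param chip,input `ReadTrack` objects on the same genome.
#' @param window_bp Window size in bp (default 200).
#' @param gap_bp Maximum gap in bp of ineligible windows bridged when
#'   clustering eligible windows into islands (default 400).
#' @param fdr Benjamini-Hochberg threshold on island q-values
#'   (default 0.001).
#' @param eligible_p Poisson upper-tail threshold for a window to be
#'   eligible (default 0.2).
#' @return A `GRanges` of islands with metadata columns `chip_count`,
#'   `input_count`, `score` (sum of -log window Poisson p over eligible
#'   windows), `p_value` and `q_value`, sorted by position.
#' @export
call_islands <- function(chip, input, window_bp = 200L, gap_bp = 400L,
                         fdr = 0.001, eligible_p = 0.2) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (gap_bp < 0) stop("gap_bp must be non-negative")
  genome <- chip$genome
  if (!identical(GenomeInfoDb::seqnames(genome),
                 GenomeInfoDb::seqnames(input$genome)))
    stop("chip and input tracks must be on the same genome")
  empty <- granges0(character(), integer(), integer(), genome,
                    chip_count = integer(), input_count = integer(),
                    score = numeric(), p_value = numeric(),
                    q_value = numeric())
  total_reads <- n_reads(chip)
  if (total_reads == 0) return(empty)

  lens <- GenomeInfoDb::seqlengths(genome)
  n_windows <- sum(ceiling(lens / window_bp))
  lambda <- total_reads / n_windows

  elig <- list()
  for (chr in GenomeInfoDb::seqnames(genome)) {
    p <- chip$positions[[chr]]
    if (is.null(p) || length(p) == 0) next
    nw <- ceiling(lens[[chr]] / window_bp)
    counts <- tabulate(p %/% window_bp + 1L, nbins = nw)
    pval <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
    keep <- which(pval <= eligible_p)
    if (length(keep) == 0) next
    st <- (keep - 1) * window_bp
    elig[[chr]] <- granges0(rep(chr, length(keep)), st,
                            pmin(st + window_bp, lens[[chr]]), genome,
                            wscore = -log(pval[keep]))
  }
  if (length(elig) == 0) return(empty)
  windows <- suppressWarnings(do.call(c, unname(elig)))

  islands <- GenomicRanges::reduce(windows, min.gapwidth = gap_bp + 1L)
  hits <- GenomicRanges::findOverlaps(windows, islands)
  score <- as.numeric(tapply(
    S4Vectors::mcols(windows)$wscore[S4Vectors::queryHits(hits)],
    factor(S4Vectors::subjectHits(hits), seq_along(islands)),
    sum, default = 0))

  chip_count <- count_reads(chip, islands)
  input_count <- count_reads(input, islands)
  expected <- input_count * chip$library_size / input$library_size
  bg <- total_reads / genome_size(genome) * BiocGenerics::width(islands)
  expected <- pmax(expected, bg)
  p_value <- stats::ppois(chip_count - 1, expected, lower.tail = FALSE)
  q_value <- stats::p.adjust(p_value, method = "BH")

  S4Vectors::mcols(islands) <- S4Vectors::DataFrame(
    chip_count = chip_count, input_count = input_count,
    score = score, p_value = p_value, q_value = q_value)
  BiocGenerics::sort(islands[q_value <= fdr])
}

#' Compare read enrichment between two conditions at fixed islands
#'
#' Per island, condition counts are compared by a two-sided binomial
#' test of `count_A` out of `count_A + count_B` against the
#' library-size-ratio null, with BH correction across islands.
#' Densities are RPBM with a pseudocount of half a read; the reported
#' `log2_fold_change` is `log2(density_A / density_B)`, so a positive
#' value means the island lost signal in condition B.
#'
#' @param islands `GRanges` of islands (non-empty).
#' @param track_A,track_B `ReadTrack` objects (e.g. control and
#'   knockdown ChIP).
#' @param fc_threshold Fold-change threshold for a call (default 1.5).
#' @param fdr BH q-value threshold (default 0.001).
#' @return `GRanges` with metadata columns `count_A`, `count_B`,
#'   `density_A`, `density_B`, `log2_fold_change`, `p_value`,
#'   `q_value` and `call` in `{increased, decreased, unaltered}`
#'   (direction refers to condition B relative to A).
#' @export
differential_islands <- function(islands, track_A, track_B,
                                 fc_threshold = 1.5, fdr = 0.001) {
  if (length(islands) == 0) stop("islands must be non-empty")
  if (n_reads(track_A) == 0 && n_reads(track_B) == 0)
    stop("both tracks are empty")
  a <- count_reads(track_A, islands)
  b <- count_reads(track_B, islands)
  w <- BiocGenerics::width(islands)
  la <- track_A$library_size
  lb <- track_B$library_size
  dens_a <- a / w / (la / 1e6)
  dens_b <- b / w / (lb / 1e6)
  eps_a <- 0.5 / w / (la / 1e6)
  eps_b <- 0.5 / w / (lb / 1e6)
  log2fc <- log2((dens_a + eps_a) / (dens_b + eps_b))
  p <- binom_p_two_sided(a, a + b, la / (la + lb))
  q <- stats::p.adjust(p, method = "BH")
  call <- rep("unaltered", length(islands))
  call[q <= fdr & log2fc >= log2(fc_threshold)] <- "decreased"
  call[q <= fdr & log2fc <= -log2(fc_threshold)] <- "increased"
  out <- islands
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    count_A = a, count_B = b,
    density_A = dens_a, density_B = dens_b,
    log2_fold_change = log2fc, p_value = p, q_value = q, call = call)
  out
}

#' Average read-density profile around anchor midpoints
#'
#' Each anchor midpoint +/- `flank_bp` is divided into `n_bins` equal
#' bins; per-bin RPBM is averaged over anchors. Anchors whose window
#' would be truncated at a chromosome edge are dropped.
#'
#' @param track A `ReadTrack`.
#' @param anchors Non-empty `GRanges` of anchor intervals.
#' @param flank_bp Half-width of the profiled window in bp.
#' @param n_bins Number of bins (>= 1).
#' @return A data.frame with one row per bin: `bin`, `rel_start` /
#'   `rel_end` (bp relative to the midpoint) and `mean_rpbm`.
#' @export
average_profile <- function(track, anchors, flank_bp, n_bins) {
  if (length(anchors) == 0) stop("anchors must be non-empty")
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (flank_bp < 1) stop("flank_bp must be >= 1")
  mid <- (start0(anchors) + end0(anchors)) %/% 2
  lens <- GenomeInfoDb::seqlengths(track$genome)[
    as.character(GenomeInfoDb::seqnames(anchors))]
  keep <- mid - flank_bp >= 0 & mid + flank_bp <= lens
  if (!any(keep)) stop("all anchors dropped at chromosome edges")
  mid <- mid[keep]
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))[keep]
  edges <- round(seq(-flank_bp, flank_bp, length.out = n_bins + 1))
  mean_rpbm <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    gr <- granges0(chrom, mid + edges[k], mid + edges[k + 1], track$genome)
    mean_rpbm[k] <- mean(compute_rpbm(track, gr))
  }
  data.frame(bin = seq_len(n_bins),
             rel_start = edges[-(n_bins + 1)],
             rel_end = edges[-1],
             mean_rpbm = mean_rpbm)
}

#' ECDF of per-island log2 density fold-changes between two tracks
#'
#' Values are `log2((density_B + eps) / (density_A + eps))` with a
#' half-read pseudocount, so a distribution shifted left of zero means
#' a systematic loss of enrichment in condition B.
#'
#' @inheritParams differential_islands
#' @return List with `values` (sorted log2 fold-changes), `frac`
#'   (cumulative fractions) and `ecdf` (a [stats::ecdf] function).
#' @export
fold_change_ecdf <- function(islands, track_A, track_B) {
  if (length(islands) == 0) stop("islands must be non-empty")
  w <- BiocGenerics::width(islands)
  dens_a <- compute_rpbm(track_A, islands)
  dens_b <- compute_rpbm(track_B, islands)
  eps_a <- 0.5 / w / (track_A$library_size / 1e6)
  eps_b <- 0.5 / w / (track_B$library_size / 1e6)
  v <- sort(log2((dens_b + eps_b) / (dens_a + eps_a)))
  list(values = v, frac = seq_along(v) / length(v), ecdf = stats::ecdf(v))
}
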