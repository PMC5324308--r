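# Interval sets are GRanges objects. Coordinates are handled in the BED
# convention (0-based half-open) at the file boundary and converted to
# the 1-based closed GRanges convention internally; all overlap and
# coverage computations are unstranded.

# 0-based start / exclusive end of a GRanges, for arithmetic in the BED
# coordinate frame.
start0 <- function(gr) BiocGenerics::start(gr) - 1L
end0 <- function(gr) BiocGenerics::end(gr)

# Build a GRanges from 0-based half-open coordinates.
granges0 <- function(chrom, start, end, genome = NULL, ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    ...)
  if (!is.null(genome)) {
    validate_on_genome(gr, genome)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' Read an interval set from a BED3/BED6 file
#'
#' Intervals are interpreted exactly as BED specifies: 0-based,
#' half-open. Optional columns 4-6 populate the name, score and strand.
#'
#' @param path Path to a tab-separated BED file without header.
#' @param genome Optional `Seqinfo` genome; when given, intervals are
#'   validated against chromosome bounds and the result carries the
#'   genome's seqinfo.
#' @return A `GRanges` object with `name` and `score` metadata columns
#'   when present in the file.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(granges0(character(), integer(), integer(), genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  if (any(end <= start))
    stop("invalid interval at line ", which(end <= start)[1],
         ": end must exceed start")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 ".")
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5, length(f))], ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6,
                   vapply(fields, function(f) f[min(6, length(f))], ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  granges0(chrom, start, end, genome, strand = strand,
           name = name, score = score)
}

#' Write an interval set to a six-column BED file
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are used
#'   when present, with `.` and `0` as defaults.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else
    rep(".", length(gr))
  score <- if ("score" %in% names(mc)) as.numeric(mc$score) else
    rep(0, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = format(start0(gr), scientific = FALSE, trim = TRUE),
                   end = format(end0(gr), scientific = FALSE, trim = TRUE),
                   name = name,
                   score = format(score, scientific = FALSE, trim = TRUE),
                   strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize an interval set: sort by (chromosome, start)
#' @param gr A `GRanges`.
#' @export
normalize_intervals <- function(gr) {
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Fraction of each query interval covered by a subject set
#'
#' Subject intervals are unioned before coverage is measured, so
#' overlapping subject elements are never double-counted. Strand is
#' ignored.
#'
#' @param query,subject `GRanges` interval sets on the same genome.
#' @return Numeric vector, one value in \[0, 1\] per query interval.
#' @export
overlap_fraction <- function(query, subject) {
  if (length(query) == 0) return(numeric(0))
  red <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, red, ignore.strand = TRUE)
  if (length(hits) == 0) return(numeric(length(query)))
  qi <- S4Vectors::queryHits(hits)
  inter <- IRanges::pintersect(query[qi], red[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  covered <- tapply(BiocGenerics::width(inter), factor(qi, seq_along(query)),
                    sum, default = 0)
  as.numeric(covered) / BiocGenerics::width(query)
}

#' Percentage of intervals in one set that overlap another set
#'
#' @param setA,setB `GRanges` interval sets.
#' @param min_overlap_bp Minimum overlap in bp for an interval of `setA`
#'   to count as overlapping (default 1; touching half-open intervals do
#'   not overlap).
#' @return Percentage in \[0, 100\] of `setA` intervals overlapping at
#'   least one `setB` interval.
#' @export
island_overlap_percent <- function(setA, setB, min_overlap_bp = 1L) {
  if (length(setA) == 0)
    stop("setA is empty: overlap percentage undefined")
  if (length(setB) == 0) return(0)
  n <- GenomicRanges::countOverlaps(setA, setB,
                                    minoverlap = min_overlap_bp,
                                    ignore.strand = TRUE)
  100 * mean(n > 0)
}

#' Sample random genomic regions matched to a template set
#'
#' For each template interval, draws `n_draws_per_region` intervals of
#' identical length, placed uniformly at random on the same chromosome.
#' This is the matched null ("random genomic sequences of comparable
#' size and frequency") against which island/repeat enrichment is
#' judged. Sampled regions may overlap each other.
#'
#' @param template `GRanges` template set.
#' @param genome `Seqinfo` genome.
#' @param n_draws_per_region Draws per template interval.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `GRanges` with a `draw` metadata column (1..n per
#'   template interval), ordered template-major.
#' @export
sample_random_regions <- function(template, genome, n_draws_per_region,
                                  seed) {
  stopifnot(n_draws_per_region >= 1)
  validate_on_genome(template, genome, "template")
  n <- as.integer(n_draws_per_region)
  lens <- GenomeInfoDb::seqlengths(genome)[
    as.character(GenomeInfoDb::seqnames(template))]
  w <- BiocGenerics::width(template)
  if (any(w > lens))
    stop("template interval longer than its chromosome")
  k <- length(template)
  if (k == 0) return(granges0(character(), integer(), integer(), genome))
  with_seed(seed, {
    # one uniform start per (template, draw), template-major order
    max_start0 <- rep(lens - w, each = n)          # inclusive upper bound
    starts <- floor(stats::runif(k * n, min = 0, max = max_start0 + 1))
    starts <- pmin(starts, max_start0)             # guard the open edge
    granges0(rep(as.character(GenomeInfoDb::seqnames(template)), each = n),
             starts, starts + rep(w, each = n), genome,
             draw = rep(seq_len(n), times = k),
             template = rep(seq_len(k), each = n))
  })
}
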