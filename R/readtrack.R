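# A ReadTrack stores mapped single-end reads as sorted 0-based start
# positions per chromosome, plus the library size used for
# per-million normalization and a fixed read length used to extend each
# read to its covered interval [pos, pos + read_length).

#' Construct a read track from per-chromosome read start positions
#'
#' @param positions Named list (one entry per chromosome) of integer
#'   vectors of 0-based read start positions, or a two-column
#'   data.frame (chrom, pos).
#' @param genome `Seqinfo` genome the reads are mapped to.
#' @param read_length Read length in bp used for coverage extension.
#' @param library_size Total mapped reads; defaults to the number of
#'   stored positions. Must be at least the number of stored positions.
#' @return An object of class `ReadTrack`.
#' @export
read_track <- function(positions, genome, read_length = 50L,
                       library_size = NULL) {
  if (is.data.frame(positions))
    positions <- split(as.numeric(positions[[2]]),
                       as.character(positions[[1]]))
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  bad <- setdiff(names(positions), GenomeInfoDb::seqnames(genome))
  if (length(bad))
    stop("read positions on chromosomes absent from genome: ",
         paste(bad, collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(genome)
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (length(p) && (min(p) < 0 || max(p) >= lens[[chr]]))
      stop("read positions outside chromosome bounds on ", chr)
  }
  n <- sum(lengths(positions))
  library_size <- library_size %||% n
  if (library_size < n)
    stop("library_size smaller than number of stored reads")
  if (read_length < 1) stop("read_length must be >= 1")
  structure(list(positions = positions, genome = genome,
                 read_length = as.integer(read_length),
                 library_size = as.numeric(library_size)),
            class = "ReadTrack")
}

#' @export
print.ReadTrack <- function(x, ...) {
  cat("ReadTrack:", sum(lengths(x$positions)), "reads on",
      length(x$positions), "chromosome(s);",
      "library size", x$library_size, ";",
      "read length", x$read_length, "bp\n")
  invisible(x)
}

#' Number of stored reads in a track
#' @param track A `ReadTrack`.
#' @export
n_reads <- function(track) sum(lengths(track$positions))

#' Read a track from a BED file of read positions
#'
#' Each BED line is one read; its start is the mapped position.
#' @inheritParams read_track
#' @param path BED file of reads.
#' @export
read_track_bed <- function(path, genome, read_length = 50L,
                           library_size = NULL) {
  gr <- read_bed(path, genome)
  read_track(split(start0(gr), as.character(GenomeInfoDb::seqnames(gr))),
             genome, read_length, library_size)
}

#' Write a track as a BED file of read intervals
#' @param track A `ReadTrack`.
#' @param path Output path.
#' @export
write_track_bed <- function(track, path) {
  chrom <- rep(names(track$positions), lengths(track$positions))
  pos <- unlist(track$positions, use.names = FALSE) %||% numeric(0)
  lens <- GenomeInfoDb::seqlengths(track$genome)[chrom]
  gr <- granges0(chrom, pos, pmin(pos + track$read_length, lens),
                 track$genome)
  write_bed(gr, path)
}

#' Count reads overlapping each of a set of intervals
#'
#' A read at position p (0-based) covers `[p, p + read_length)` and
#' overlaps an interval `[s, e)` iff `p > s - read_length` and `p < e`.
#' Counting is done by binary search on the sorted position vectors.
#'
#' @param track A `ReadTrack`.
#' @param gr A `GRanges` of intervals.
#' @return Integer vector of read counts, one per interval.
#' @export
count_reads <- function(track, gr) {
  out <- integer(length(gr))
  if (length(gr) == 0) return(out)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  s <- start0(gr)
  e <- end0(gr)
  rl <- track$read_length
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    p <- track$positions[[chr]]
    if (is.null(p) || length(p) == 0) next
    # reads with position in [s - rl + 1, e - 1]
    out[idx] <- findInterval(e[idx] - 1, p) - findInterval(s[idx] - rl, p)
  }
  out
}

#' RPBM read density over intervals
#'
#' RPBM (reads per base per million mapped reads) quantifies ChIP or
#' RNA read density at a genomic region:
#' `count / interval_length / (library_size / 1e6)`.
#'
#' @param track A `ReadTrack`.
#' @param gr A `GRanges` of intervals (all widths >= 1).
#' @return Numeric vector of RPBM densities, one per interval.
#' @export
compute_rpbm <- function(track, gr) {
  if (track$library_size <= 0) stop("library_size must be positive")
  w <- BiocGenerics::width(gr)
  if (any(w < 1)) stop("zero-length interval")
  count_reads(track, gr) / w / (track$library_size / 1e6)
}
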