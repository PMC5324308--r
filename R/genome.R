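#' Define a genome as a set of named chromosomes with lengths
#'
#' The genome is the coordinate space every interval set, read track and
#' annotation is bound to. It is represented as a
#' [GenomeInfoDb::Seqinfo] object, the standard Bioconductor container
#' for chromosome names and lengths.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all >= 1).
#' @return A `Seqinfo` object.
#' @examples
#' g <- make_genome(c("chr1", "chr2"), c(2e6, 1e6))
#' genome_size(g)
#' @export
make_genome <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("all chromosome lengths must be >= 1")
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Total genome size in bp
#' @param genome A `Seqinfo` genome.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Read a genome from a two-column chrom-sizes file
#'
#' @param path Tab-separated file with columns: chromosome name, length.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  make_genome(df$chrom, df$length)
}

#' Write a genome as a two-column chrom-sizes file
#' @param genome A `Seqinfo` genome.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  df <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                   length = GenomeInfoDb::seqlengths(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Check that a GRanges is bound to (a superset of) the given genome and
# that intervals respect chromosome bounds.
validate_on_genome <- function(gr, genome, what = "interval set") {
  bad <- !(as.character(GenomeInfoDb::seqnames(gr)) %in%
             GenomeInfoDb::seqnames(genome))
  if (any(bad))
    stop(what, " uses chromosomes absent from the genome: ",
         paste(unique(as.character(GenomeInfoDb::seqnames(gr))[bad]),
               collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(genome)[
    as.character(GenomeInfoDb::seqnames(gr))]
  if (any(BiocGenerics::end(gr) > lens) || any(BiocGenerics::start(gr) < 1))
    stop(what, " has intervals outside chromosome bounds")
  invisible(TRUE)
}
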