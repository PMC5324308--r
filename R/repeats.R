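# Repeat-element annotation with the RepeatMasker class -> family ->
# subfamily (name) hierarchy, and enrichment of island sets in repeat
# labels against matched random-region nulls.

REPEAT_LEVELS <- c("class", "family", "name")

#' Construct a repeat annotation
#'
#' @param gr `GRanges` of repeat elements.
#' @param repeat_class,repeat_family,repeat_name Character vectors (one
#'   per element) with the class (e.g. LINE, LTR), family (e.g. L1,
#'   ERVK) and subfamily name (e.g. L1Md_T, IAPLTR2_Mm). Each name must
#'   map to exactly one family and each family to one class.
#' @return A `GRanges` of class-extended type `RepeatAnnotation` with
#'   metadata columns `repeat_class`, `repeat_family`, `repeat_name`.
#' @export
repeat_annotation <- function(gr, repeat_class, repeat_family, repeat_name) {
  stopifnot(length(gr) == length(repeat_class),
            length(gr) == length(repeat_family),
            length(gr) == length(repeat_name))
  # the hierarchy must be functional: name -> family -> class
  nf <- unique(data.frame(n = repeat_name, f = repeat_family))
  fc <- unique(data.frame(f = repeat_family, c = repeat_class))
  if (anyDuplicated(nf$n))
    stop("repeat name mapped to more than one family")
  if (anyDuplicated(fc$f))
    stop("repeat family mapped to more than one class")
  S4Vectors::mcols(gr)$repeat_class <- as.character(repeat_class)
  S4Vectors::mcols(gr)$repeat_family <- as.character(repeat_family)
  S4Vectors::mcols(gr)$repeat_name <- as.character(repeat_name)
  gr
}

#' Read a repeat annotation from a BED6+3 file
#'
#' Columns 7-9 carry repeat class, family and name.
#' @param path BED6+3 file.
#' @param genome Optional `Seqinfo` genome.
#' @export
read_repeat_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 9)
    stop("repeat BED must have 9 columns (BED6 + class/family/name)")
  gr <- granges0(df[[1]], df[[2]], df[[3]], genome,
                 name = as.character(df[[4]]), score = df[[5]],
                 strand = ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*"))
  repeat_annotation(gr, df[[7]], df[[8]], df[[9]])
}

#' Write a repeat annotation as BED6+3
#' @param repeats A repeat annotation `GRanges`.
#' @param path Output path.
#' @export
write_repeat_bed <- function(repeats, path) {
  mc <- S4Vectors::mcols(repeats)
  strand <- as.character(BiocGenerics::strand(repeats))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(repeats)),
                   start = start0(repeats), end = end0(repeats),
                   name = mc$repeat_name, score = 0, strand = strand,
                   repeat_class = mc$repeat_class,
                   repeat_family = mc$repeat_family,
                   repeat_name = mc$repeat_name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker .out-style table
#'
#' Whitespace-separated table with the standard three header lines;
#' the class/family column ("LINE/L1") is split into the hierarchy and
#' coordinates (1-based closed) are converted to the internal
#' convention.
#' @param path RepeatMasker .out file.
#' @param genome Optional `Seqinfo` genome.
#' @export
read_repeatmasker_out <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0)
    stop("no repeat records in ", path)
  f <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(f) < 11))
    stop("malformed RepeatMasker line ", which(lengths(f) < 11)[1])
  chrom <- vapply(f, `[[`, "", 5L)
  start1 <- as.numeric(vapply(f, `[[`, "", 6L))
  end1 <- as.numeric(vapply(f, `[[`, "", 7L))
  name <- vapply(f, `[[`, "", 10L)
  clsfam <- vapply(f, `[[`, "", 11L)
  cls <- sub("/.*$", "", clsfam)
  fam <- ifelse(grepl("/", clsfam), sub("^[^/]*/", "", clsfam), clsfam)
  gr <- granges0(chrom, start1 - 1, end1, genome, name = name, score = 0)
  repeat_annotation(gr, cls, fam, name)
}

# Elements carrying a given label at a given hierarchy level.
repeat_subset <- function(repeats, level, key) {
  level <- match.arg(level, REPEAT_LEVELS)
  col <- paste0("repeat_", level)
  labels <- S4Vectors::mcols(repeats)[[col]]
  if (!key %in% labels)
    stop("unknown ", level, " '", key, "'; available: ",
         paste(sort(unique(labels)), collapse = ", "))
  repeats[labels == key]
}

#' Labels present at a hierarchy level
#' @param repeats A repeat annotation `GRanges`.
#' @param level One of `"class"`, `"family"`, `"name"`.
#' @export
repeat_keys <- function(repeats, level = "name") {
  level <- match.arg(level, REPEAT_LEVELS)
  sort(unique(S4Vectors::mcols(repeats)[[paste0("repeat_", level)]]))
}

#' Per-island fraction covered by a repeat label
#'
#' For each island, the fraction of its bases covered by the union of
#' repeat elements carrying the given label ("percent coverage").
#' Overlapping elements of the same label are merged first.
#'
#' @param islands `GRanges` of islands.
#' @param repeats Repeat annotation `GRanges`.
#' @param level Hierarchy level (`"class"`, `"family"`, `"name"`).
#' @param key Label at that level (e.g. "LINE", "L1", "IAPLTR2_Mm").
#' @return Numeric vector of fractions in \[0, 1\], one per island.
#' @export
percent_coverage_per_island <- function(islands, repeats, level, key) {
  overlap_fraction(islands, repeat_subset(repeats, level, key))
}

#' Two-sample ECDF/Kolmogorov-Smirnov enrichment comparison
#'
#' Compares observed per-island coverages against coverages of matched
#' random regions: D is the sup-gap between the two ECDFs, the p-value
#' is the asymptotic two-sided KS p, and the direction is `enriched`
#' when the observed mean exceeds the null mean.
#'
#' @param observed,null Non-empty numeric vectors of per-region
#'   coverage fractions.
#' @param level,key Optional labels carried through to the result.
#' @return An object of class `EnrichmentResult` (a list) with fields
#'   `ks_statistic`, `ks_p_value`, `direction`, `observed_mean`,
#'   `null_mean`, `n_observed`, `n_null` and the labels.
#' @export
ecdf_ks_enrichment <- function(observed, null, level = NA_character_,
                               key = NA_character_) {
  if (length(observed) == 0 || length(null) == 0)
    stop("observed and null vectors must be non-empty")
  kt <- suppressWarnings(stats::ks.test(observed, null, exact = FALSE))
  mo <- mean(observed)
  mn <- mean(null)
  direction <- if (kt$statistic == 0 || mo == mn) "none" else
    if (mo > mn) "enriched" else "depleted"
  structure(list(level = level, key = key,
                 ks_statistic = unname(kt$statistic),
                 ks_p_value = unname(kt$p.value),
                 direction = direction,
                 observed_mean = mo, null_mean = mn,
                 n_observed = length(observed), n_null = length(null)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult %s/%s: D = %.4f, p = %.3g, %s (obs mean %.4f vs null %.4f)\n",
    x$level, x$key, x$ks_statistic, x$ks_p_value, x$direction,
    x$observed_mean, x$null_mean))
  invisible(x)
}

#' Percentage of islands overlapping each repeat label
#'
#' @inheritParams percent_coverage_per_island
#' @return data.frame with `key`, `n_elements` and `percent_overlap`,
#'   sorted by descending percentage.
#' @export
peak_overlap_percentage <- function(islands, repeats, level = "family") {
  if (length(islands) == 0) stop("islands must be non-empty")
  level <- match.arg(level, REPEAT_LEVELS)
  keys <- repeat_keys(repeats, level)
  pct <- vapply(keys, function(k) {
    sub <- repeat_subset(repeats, level, k)
    island_overlap_percent(islands, sub)
  }, 0)
  n <- vapply(keys, function(k)
    length(repeat_subset(repeats, level, k)), 0L)
  out <- data.frame(key = keys, n_elements = n, percent_overlap = pct,
                    row.names = NULL)
  out[order(-out$percent_overlap, out$key), , drop = FALSE]
}

#' Subfamily enrichment ratios of island sets over matched random draws
#'
#' For each island set and repeat label, the ratio of the observed
#' percentage of islands overlapping the label to the mean percentage
#' over matched random-region draws (each draw is one full matched
#' copy of the island set). The null mean is floored at a small
#' percentage to keep ratios finite.
#'
#' @param island_sets Named list of `GRanges` island sets.
#' @param repeats Repeat annotation `GRanges`.
#' @param genome `Seqinfo` genome for the random draws.
#' @param n_draws Matched random draws per island set (default 10).
#' @param seed Integer seed.
#' @param level Hierarchy level (default `"name"`).
#' @param floor_pct Floor on the null overlap percentage (default
#'   0.25).
#' @return Matrix of enrichment ratios, rows = repeat labels, columns =
#'   island sets; attributes `observed` and `null` carry the underlying
#'   percentages.
#' @export
subfamily_enrichment_matrix <- function(island_sets, repeats, genome,
                                        n_draws = 10L, seed = 1L,
                                        level = "name", floor_pct = 0.25) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (length(island_sets) == 0) stop("need at least one island set")
  level <- match.arg(level, REPEAT_LEVELS)
  keys <- repeat_keys(repeats, level)
  subs <- lapply(keys, function(k) repeat_subset(repeats, level, k))
  obs <- nul <- matrix(NA_real_, length(keys), length(island_sets),
                       dimnames = list(keys, names(island_sets)))
  for (j in seq_along(island_sets)) {
    isl <- island_sets[[j]]
    rand <- sample_random_regions(isl, genome, n_draws,
                                  derive_seed(seed, paste0("draws", j)))
    draw <- S4Vectors::mcols(rand)$draw
    for (i in seq_along(keys)) {
      obs[i, j] <- island_overlap_percent(isl, subs[[i]])
      per_draw <- vapply(seq_len(n_draws), function(d)
        island_overlap_percent(rand[draw == d], subs[[i]]), 0)
      nul[i, j] <- mean(per_draw)
    }
  }
  ratio <- obs / pmax(nul, floor_pct)
  attr(ratio, "observed") <- obs
  attr(ratio, "null") <- nul
  ratio
}
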