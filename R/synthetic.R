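# Synthetic data with known ground truth: a toy multi-chromosome
# genome, a hierarchical repeat annotation, ChIP/Input/RNA read tracks
# with planted enrichment, and a two-genotype differentiation
# expression time course. Everything is deterministic given its seed,
# so every downstream stage can be tested against the planted truth.

#' Generate a toy genome
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_length Length of each chromosome in bp (default 2 Mb);
#'   recycled if scalar.
#' @param seed Unused placeholder kept for interface symmetry; the
#'   genome is deterministic.
#' @return A `Seqinfo` genome with chromosomes `chr1..chrN`.
#' @export
generate_genome <- function(n_chroms = 3L, chrom_length = 2e6, seed = 1L) {
  lens <- rep_len(chrom_length, n_chroms)
  if (any(lens < 1e4)) stop("chromosome lengths must be >= 10 kb")
  make_genome(paste0("chr", seq_len(n_chroms)), lens)
}

#' Default repeat-subfamily configuration
#'
#' Twenty subfamilies in a RepeatMasker-like hierarchy (LINE/L1,
#' LTR/ERVK, LTR/ERV1, SINE/B1|B2, DNA/hAT), with element counts and
#' lengths loosely shaped like a young mouse repeat complement.
#' `co_placement` is the probability that an element is placed
#' overlapping a planted island rather than uniformly.
#' @return data.frame with columns `name`, `family`, `class`, `count`,
#'   `length`, `co_placement`.
#' @export
default_repeat_config <- function() {
  cfg <- rbind(
    data.frame(name = "L1Md_T_syn",    family = "L1",   class = "LINE", count = 120, length = 900),
    data.frame(name = "L1Md_A_syn",    family = "L1",   class = "LINE", count = 100, length = 700),
    data.frame(name = "L1Md_F2_syn",   family = "L1",   class = "LINE", count = 80,  length = 600),
    data.frame(name = "L1_Mus3_syn",   family = "L1",   class = "LINE", count = 80,  length = 500),
    data.frame(name = "Lx5_syn",       family = "L1",   class = "LINE", count = 60,  length = 450),
    data.frame(name = "IAPLTR1_syn",   family = "ERVK", class = "LTR",  count = 90,  length = 350),
    data.frame(name = "IAPLTR2_syn",   family = "ERVK", class = "LTR",  count = 70,  length = 350),
    data.frame(name = "IAPEz_int_syn", family = "ERVK", class = "LTR",  count = 50,  length = 1500),
    data.frame(name = "ETnERV2_int_syn", family = "ERVK", class = "LTR", count = 40, length = 1200),
    data.frame(name = "MMETn_int_syn", family = "ERVK", class = "LTR",  count = 40,  length = 800),
    data.frame(name = "RLTR10_int_syn", family = "ERVK", class = "LTR", count = 40,  length = 700),
    data.frame(name = "MMERVK10C_syn", family = "ERVK", class = "LTR",  count = 40,  length = 900),
    data.frame(name = "RLTR4_syn",     family = "ERV1", class = "LTR",  count = 50,  length = 400),
    data.frame(name = "RLTR6_syn",     family = "ERV1", class = "LTR",  count = 40,  length = 450),
    data.frame(name = "MuLV_int_syn",  family = "ERV1", class = "LTR",  count = 30,  length = 1400),
    data.frame(name = "B1_Mus1_syn",   family = "B1",   class = "SINE", count = 250, length = 150),
    data.frame(name = "B2_Mm1a_syn",   family = "B2",   class = "SINE", count = 200, length = 190),
    data.frame(name = "B2_Mm2_syn",    family = "B2",   class = "SINE", count = 150, length = 180),
    data.frame(name = "MER1_syn",      family = "hAT",  class = "DNA",  count = 80,  length = 250),
    data.frame(name = "Charlie1_syn",  family = "hAT",  class = "DNA",  count = 60,  length = 300))
  cfg$co_placement <- 0
  # two heterochromatin-prone subfamilies co-placed with planted islands
  cfg$co_placement[cfg$name == "L1Md_T_syn"] <- 0.9
  cfg$co_placement[cfg$name == "IAPLTR2_syn"] <- 0.9
  cfg
}

#' Place non-overlapping planted islands on a genome
#'
#' @param genome `Seqinfo` genome.
#' @param n_islands Number of islands (default 60).
#' @param island_width Island width in bp (default 2500, a typical
#'   broad heterochromatin domain).
#' @param min_gap_bp Minimum spacing between islands (default 2000),
#'   so planted domains are mutually resolvable.
#' @param seed Integer seed.
#' @return `GRanges` of pairwise non-overlapping islands, sorted.
#' @export
generate_planted_islands <- function(genome, n_islands = 60L,
                                     island_width = 2500L,
                                     min_gap_bp = 2000L, seed = 1L) {
  lens <- GenomeInfoDb::seqlengths(genome)
  w <- as.numeric(island_width)
  m <- as.numeric(min_gap_bp)
  capacity <- function(n, L) n * w + max(n - 1, 0) * m <= L
  with_seed(seed, {
    # allocate island counts to chromosomes by length, respecting
    # per-chromosome capacity
    alloc <- NULL
    for (tries in 1:100) {
      cand <- table(factor(sample(names(lens), n_islands, replace = TRUE,
                                  prob = as.numeric(lens)),
                           levels = names(lens)))
      if (all(mapply(capacity, as.numeric(cand), as.numeric(lens)))) {
        alloc <- cand
        break
      }
    }
    if (is.null(alloc))
      stop("could not place non-overlapping islands: genome too small")
    parts <- lapply(names(lens), function(chr) {
      n <- as.numeric(alloc[[chr]])
      if (n == 0) return(NULL)
      # sorted uniform slack + fixed offsets gives uniformly placed,
      # ordered islands with the required spacing
      slack <- lens[[chr]] - n * w - (n - 1) * m
      u <- sort(floor(stats::runif(n, 0, slack + 1)))
      start <- u + (seq_len(n) - 1) * (w + m)
      granges0(rep(chr, n), start, start + w, genome)
    })
    out <- suppressWarnings(do.call(c, Filter(Negate(is.null), parts)))
    out <- BiocGenerics::sort(out)
    S4Vectors::mcols(out)$name <- paste0("island_", seq_along(out))
    out
  })
}

#' Generate a hierarchical repeat annotation
#'
#' Elements of each configured subfamily are placed uniformly on the
#' genome, except that with probability `co_placement` an element is
#' placed so that it overlaps a randomly chosen planted island.
#'
#' @param genome `Seqinfo` genome.
#' @param config data.frame as in [default_repeat_config()].
#' @param islands Optional `GRanges` of planted islands (required when
#'   any `co_placement` > 0).
#' @param seed Integer seed.
#' @return A repeat annotation `GRanges`.
#' @export
generate_repeat_annotation <- function(genome, config, islands = NULL,
                                       seed = 1L) {
  if (nrow(config) == 0) stop("empty repeat configuration")
  if (sum(config$count * config$length) > 0.8 * genome_size(genome))
    stop("requested repeat elements exceed genome capacity")
  co <- config$co_placement %||% rep(0, nrow(config))
  if (any(co > 0) && (is.null(islands) || length(islands) == 0))
    stop("co_placement > 0 requires planted islands")
  lens <- GenomeInfoDb::seqlengths(genome)
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(config)), function(i) {
      n <- config$count[i]
      L <- config$length[i]
      near <- stats::runif(n) < co[i]
      chrom <- character(n)
      start <- numeric(n)
      if (any(near)) {
        k <- sample.int(length(islands), sum(near), replace = TRUE)
        ic <- as.character(GenomeInfoDb::seqnames(islands))[k]
        lo <- pmax(start0(islands)[k] - L + 1, 0)
        hi <- pmin(end0(islands)[k] - 1, lens[ic] - L)
        chrom[near] <- ic
        start[near] <- floor(stats::runif(sum(near), lo, hi + 1))
      }
      if (any(!near)) {
        c2 <- sample(names(lens), sum(!near), replace = TRUE,
                     prob = as.numeric(lens))
        chrom[!near] <- c2
        start[!near] <- floor(stats::runif(sum(!near), 0, lens[c2] - L + 1))
      }
      granges0(chrom, start, start + L, genome,
               strand = sample(c("+", "-"), n, replace = TRUE),
               repeat_class = config$class[i],
               repeat_family = config$family[i],
               repeat_name = config$name[i])
    })
    gr <- BiocGenerics::sort(suppressWarnings(do.call(c, unname(parts))),
                             ignore.strand = TRUE)
    repeat_annotation(gr, S4Vectors::mcols(gr)$repeat_class,
                      S4Vectors::mcols(gr)$repeat_family,
                      S4Vectors::mcols(gr)$repeat_name)
  })
}

# Poisson reads on a piecewise-constant rate: background everywhere,
# `fold` times background inside the given islands.
poisson_reads <- function(genome, islands, fold_per_island,
                          background_rate, read_length) {
  lens <- GenomeInfoDb::seqlengths(genome)
  pos <- stats::setNames(vector("list", length(lens)), names(lens))
  for (chr in names(lens)) {
    Lc <- lens[[chr]]
    n_bg <- stats::rpois(1, background_rate * Lc)
    p <- floor(stats::runif(n_bg, 0, Lc))
    sel <- which(as.character(GenomeInfoDb::seqnames(islands)) == chr)
    for (k in sel) {
      w <- end0(islands)[k] - start0(islands)[k]
      extra_rate <- background_rate * (fold_per_island[k] - 1)
      if (extra_rate > 0) {
        n_ex <- stats::rpois(1, extra_rate * w)
        p <- c(p, floor(stats::runif(n_ex, start0(islands)[k],
                                     end0(islands)[k])))
      } else if (extra_rate < 0) {
        # attenuated below background: thin background reads inside
        inside <- p >= start0(islands)[k] & p < end0(islands)[k]
        keep_p <- fold_per_island[k]
        drop <- inside & stats::runif(length(p)) > keep_p
        p <- p[!drop]
      }
    }
    pos[[chr]] <- sort(pmin(p, Lc - 1))
  }
  read_track(pos, genome, read_length)
}

#' Generate ChIP, knockdown-ChIP and Input read tracks
#'
#' Reads are Poisson-placed: the Input track at `background_rate`
#' everywhere; the control ChIP at `background_rate * enrichment_fold`
#' inside the planted islands; the knockdown ChIP with the enrichment
#' multiplied by the per-island attenuation factor.
#'
#' @param genome `Seqinfo` genome.
#' @param planted_islands `GRanges` of planted islands.
#' @param enrichment_fold Fold enrichment inside islands (default 10).
#' @param background_rate Background read rate in reads/bp (default
#'   0.008, matching typical mammalian ChIP depth; about 48k reads on
#'   the 6 Mb default genome).
#' @param attenuation Numeric vector, one factor per island, applied to
#'   the knockdown enrichment (1 = unchanged; default all 1).
#' @param read_length Read length in bp (default 50).
#' @param seed Integer seed.
#' @return List of `ReadTrack`s: `chip_ctrl`, `chip_kd`, `input`.
#' @export
generate_chip_tracks <- function(genome, planted_islands,
                                 enrichment_fold = 10,
                                 background_rate = 0.008,
                                 attenuation = NULL,
                                 read_length = 50L, seed = 1L) {
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  n <- length(planted_islands)
  attenuation <- attenuation %||% rep(1, n)
  if (length(attenuation) != n)
    stop("one attenuation factor per island required")
  with_seed(seed, {
    list(
      chip_ctrl = poisson_reads(genome, planted_islands,
                                rep(enrichment_fold, n),
                                background_rate, read_length),
      chip_kd = poisson_reads(genome, planted_islands,
                              pmax(enrichment_fold * attenuation, 0),
                              background_rate, read_length),
      input = poisson_reads(genome, planted_islands, rep(1, n),
                            background_rate, read_length))
  })
}

#' Generate a two-genotype differentiation expression time course
#'
#' Baseline gene abundances are log-normal; each gene follows a
#' geometric per-stage trajectory (up-, down-regulated or flat during
#' differentiation). The knockdown equals the control except for
#' planted DE genes (a per-gene fold applied at every stage) and
#' planted accelerated genes, whose knockdown mean at stage s is the
#' control mean at stage s+1 (the last stage maps to itself). Counts
#' are negative-binomial.
#'
#' @param n_genes Number of genes (default 5000).
#' @param stages Ordered stage labels (default ESC, EB_d6, EB_d10).
#' @param de_fraction Fraction of planted DE genes (default 0.05).
#' @param accel_fraction Fraction of planted accelerated genes
#'   (default 0.1); `de_fraction + accel_fraction` must be <= 1.
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param lib_size Target reads per sample (default 2e7).
#' @param up_fraction,down_fraction Fractions of genes up-/down-
#'   regulated across the differentiation time course (defaults 0.3).
#' @param seed Integer seed.
#' @return List with `em` (an `ExpressionMatrix`), `design`
#'   (data.frame), and `truth` (list with `de_gene_ids`, `de_fold`
#'   (log2), `accelerated_gene_ids`, `trajectory`, per-stage mean
#'   matrices `mu_ctrl` / `mu_kd`, and `seed`).
#' @export
generate_expression_timecourse <- function(n_genes = 5000L,
                                           stages = c("ESC", "EB_d6",
                                                      "EB_d10"),
                                           de_fraction = 0.05,
                                           accel_fraction = 0.1,
                                           dispersion = 0.1,
                                           lib_size = 2e7,
                                           up_fraction = 0.3,
                                           down_fraction = 0.3,
                                           seed = 1L) {
  if (de_fraction < 0 || accel_fraction < 0 ||
      de_fraction + accel_fraction > 1)
    stop("de_fraction and accel_fraction must be in [0,1] and sum <= 1")
  S <- length(stages)
  if (S < 2) stop("need at least two stages")
  with_seed(seed, {
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    lengths <- stats::setNames(round(stats::runif(n_genes, 500, 5000)),
                               gene_ids)
    base <- stats::rlnorm(n_genes, meanlog = 2, sdlog = 1)  # ~RPKM scale
    type <- sample(c("up", "down", "flat"), n_genes, replace = TRUE,
                   prob = c(up_fraction, down_fraction,
                            1 - up_fraction - down_fraction))
    fold <- stats::runif(n_genes, 2, 8)
    expo <- outer(rep(1, n_genes), seq(0, 1, length.out = S))
    traj <- fold^expo
    traj[type == "down", ] <- (1 / fold[type == "down"])^
      expo[type == "down", , drop = FALSE]
    traj[type == "flat", ] <- 1
    mu_ctrl <- base * traj
    dimnames(mu_ctrl) <- list(gene_ids, stages)
    mu_kd <- mu_ctrl

    planted <- sample.int(n_genes,
                          round(n_genes * (de_fraction + accel_fraction)))
    de_idx <- planted[seq_len(round(n_genes * de_fraction))]
    accel_idx <- setdiff(planted, de_idx)
    de_log2fc <- numeric(0)
    if (length(de_idx)) {
      de_log2fc <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
        stats::runif(length(de_idx), 1, 3)
      mu_kd[de_idx, ] <- mu_kd[de_idx, , drop = FALSE] * 2^de_log2fc
    }
    if (length(accel_idx)) {
      shifted <- mu_ctrl[accel_idx, c(2:S, S), drop = FALSE]
      mu_kd[accel_idx, ] <- shifted
    }

    draw <- function(mu) {
      # scale expected RPKM-like means to expected counts at lib_size
      w <- mu * (lengths / 1e3)
      cnt <- stats::rnbinom(n_genes, mu = w / sum(w) * lib_size,
                            size = 1 / dispersion)
      cnt
    }
    samples <- c(paste0("ctrl_", stages), paste0("kd_", stages))
    counts <- matrix(0L, n_genes, 2 * S,
                     dimnames = list(gene_ids, samples))
    for (s in seq_len(S)) {
      counts[, s] <- draw(mu_ctrl[, s])
      counts[, S + s] <- draw(mu_kd[, s])
    }
    design <- data.frame(
      sample_id = samples,
      genotype = rep(c("control", "knockdown"), each = S),
      stage = rep(stages, 2))
    truth <- list(de_gene_ids = gene_ids[de_idx],
                  de_log2fc = stats::setNames(de_log2fc, gene_ids[de_idx]),
                  accelerated_gene_ids = gene_ids[accel_idx],
                  trajectory = stats::setNames(type, gene_ids),
                  mu_ctrl = mu_ctrl, mu_kd = mu_kd, seed = seed)
    list(em = expression_matrix(counts, lengths), design = design,
         truth = truth)
  })
}

#' Generate RNA read tracks over repeat elements
#'
#' Control reads are placed in repeat elements at a base per-bp rate
#' (90% of the requested depth spread over the annotated element bp);
#' knockdown element reads are scaled by the per-subfamily
#' de-repression fold; both tracks carry uniform background
#' transcription noise (10% of depth).
#'
#' @param genome `Seqinfo` genome.
#' @param repeats Repeat annotation `GRanges`.
#' @param de_repressed Named numeric vector of fold-changes per repeat
#'   subfamily name (missing names default to 1; folds >= 0).
#' @param depth Target reads per track (default 2e5).
#' @param read_length Read length in bp (default 50).
#' @param seed Integer seed.
#' @return List of `ReadTrack`s `rna_ctrl`, `rna_kd`.
#' @export
generate_rna_repeat_reads <- function(genome, repeats,
                                      de_repressed = numeric(0),
                                      depth = 2e5, read_length = 50L,
                                      seed = 1L) {
  if (any(de_repressed < 0)) stop("de-repression folds must be >= 0")
  if (depth == 0) {
    empty <- read_track(stats::setNames(list(), character()), genome,
                        read_length)
    return(list(rna_ctrl = empty, rna_kd = empty))
  }
  lens <- GenomeInfoDb::seqlengths(genome)
  nm <- S4Vectors::mcols(repeats)$repeat_name
  fold <- stats::setNames(rep(1, length(repeats)), nm)
  hit <- nm %in% names(de_repressed)
  fold[hit] <- de_repressed[nm[hit]]
  base_rate <- 0.9 * depth / sum(BiocGenerics::width(repeats))
  noise_rate <- 0.1 * depth / genome_size(genome)
  one_track <- function(elem_fold) {
    pos <- stats::setNames(vector("list", length(lens)), names(lens))
    chrom <- as.character(GenomeInfoDb::seqnames(repeats))
    for (chr in names(lens)) {
      p <- floor(stats::runif(stats::rpois(1, noise_rate * lens[[chr]]),
                              0, lens[[chr]]))
      sel <- which(chrom == chr)
      if (length(sel)) {
        w <- BiocGenerics::width(repeats)[sel]
        n_el <- stats::rpois(length(sel), base_rate * elem_fold[sel] * w)
        if (sum(n_el) > 0) {
          idx <- rep(sel, n_el)
          p <- c(p, floor(stats::runif(sum(n_el), start0(repeats)[idx],
                                       end0(repeats)[idx])))
        }
      }
      pos[[chr]] <- sort(p)
    }
    read_track(pos, genome, read_length)
  }
  with_seed(seed, list(rna_ctrl = one_track(rep(1, length(repeats))),
                       rna_kd = one_track(unname(fold))))
}

#' Generate gene-exchangeable input for the ordering statistic
#'
#' Draws the three expression vectors iid log-normal across genes (the
#' exchangeable situation the shuffle null models), then plants
#' acceleration in a fraction of genes by drawing their knockdown EB
#' value ahead of the control trajectory (above both the ES and the
#' control EB value), so those genes cannot lag.
#'
#' @param n_genes Number of genes (default 5000).
#' @param accel_fraction Fraction of planted accelerated genes
#'   (default 0).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the expression
#'   marginal (defaults 2, 1).
#' @return List with `input` (an `OrderingInput`) and
#'   `accelerated_idx` (integer indices of the planted genes).
#' @export
generate_ordering_input <- function(n_genes = 5000L, accel_fraction = 0,
                                    seed = 1L, meanlog = 2, sdlog = 1) {
  if (accel_fraction < 0 || accel_fraction > 1)
    stop("accel_fraction must be in [0, 1]")
  with_seed(seed, {
    esc <- stats::rlnorm(n_genes, meanlog, sdlog)
    eb_ctrl <- stats::rlnorm(n_genes, meanlog, sdlog)
    eb_kd <- stats::rlnorm(n_genes, meanlog, sdlog)
    idx <- sort(sample.int(n_genes, round(n_genes * accel_fraction)))
    if (length(idx))
      eb_kd[idx] <- pmax(esc[idx], eb_ctrl[idx]) *
        stats::runif(length(idx), 1.5, 3)
    list(input = ordering_input(esc, eb_ctrl, eb_kd),
         accelerated_idx = idx)
  })
}

#' Deterministic synthetic gene models over a genome
#'
#' Lays the given genes out in order with evenly spaced midpoints
#' across the concatenated genome, alternating strands. Spans are
#' capped at half the per-gene slot so that intergenic space remains,
#' and each gene gets two exons (its first and last quarter), giving
#' the full exonic/intronic/intergenic context repertoire.
#'
#' @param genome `Seqinfo` genome.
#' @param gene_ids Character vector of gene ids.
#' @param gene_lengths Span lengths in bp (recycled; capped at half
#'   the per-gene slot).
#' @return A `GeneModels` object.
#' @export
generate_gene_models <- function(genome, gene_ids, gene_lengths = 2000) {
  lens <- GenomeInfoDb::seqlengths(genome)
  n <- length(gene_ids)
  total <- genome_size(genome)
  offs <- cumsum(c(0, as.numeric(lens)))
  mid <- (seq_len(n) - 0.5) / n * total
  ci <- findInterval(mid, offs)
  local <- floor(mid - offs[ci])
  span <- pmin(rep_len(as.numeric(gene_lengths), n),
               max(floor(0.5 * total / n), 200))
  start <- pmax(local - span %/% 2, 0)
  end <- pmin(start + span, lens[names(lens)[ci]])
  genes <- data.frame(gene_id = gene_ids, chrom = names(lens)[ci],
                      start = start, end = end,
                      strand = rep(c("+", "-"), length.out = n))
  # two short terminal exons (10% of the span each); note the toy
  # scale compresses genes, so context frequencies are not meant to
  # match real genomes
  q <- pmax((end - start) %/% 10, 1)
  exons <- rbind(
    data.frame(gene_id = gene_ids, start = start, end = start + q),
    data.frame(gene_id = gene_ids, start = end - q, end = end))
  gene_models(genes, exons)
}

#' Relocate de-repressed elements near upregulated gene TSSs
#'
#' Plants the element-to-gene coupling: each element of the given
#' subfamilies is, with probability `coupling_prob`, moved so that it
#' lies within `max_offset_bp` of the TSS of a randomly chosen target
#' gene. Returns the modified annotation plus the coupling map.
#'
#' @param repeats Repeat annotation `GRanges`.
#' @param subfamilies Subfamily names whose elements are coupled.
#' @param models `GeneModels` of the target genes.
#' @param target_gene_ids Gene ids to couple to (e.g. planted
#'   upregulated DE genes).
#' @param coupling_prob Per-element relocation probability
#'   (default 0.5).
#' @param max_offset_bp Maximum distance from the TSS (default 5000).
#' @param seed Integer seed.
#' @return List with `repeats` (re-sorted annotation) and `coupling`
#'   (data.frame element/subfamily/gene_id), empty when there are no
#'   target genes.
#' @export
couple_elements_to_genes <- function(repeats, subfamilies, models,
                                     target_gene_ids,
                                     coupling_prob = 0.5,
                                     max_offset_bp = 5000L, seed = 1L) {
  g <- models$genes[models$genes$gene_id %in% target_gene_ids, ,
                    drop = FALSE]
  if (nrow(g) == 0)
    return(list(repeats = repeats,
                coupling = data.frame(element = integer(),
                                      subfamily = character(),
                                      gene_id = character())))
  genome <- GenomeInfoDb::seqinfo(repeats)
  lens <- GenomeInfoDb::seqlengths(genome)
  nm <- S4Vectors::mcols(repeats)$repeat_name
  with_seed(seed, {
    cand <- which(nm %in% subfamilies &
                    stats::runif(length(repeats)) < coupling_prob)
    if (length(cand) == 0)
      return(list(repeats = repeats,
                  coupling = data.frame(element = integer(),
                                        subfamily = character(),
                                        gene_id = character())))
    tgt <- sample.int(nrow(g), length(cand), replace = TRUE)
    w <- BiocGenerics::width(repeats)[cand]
    off <- floor(stats::runif(length(cand), -max_offset_bp,
                              max_offset_bp - w + 1))
    start <- pmax(pmin(g$tss[tgt] + off, lens[g$chrom[tgt]] - w), 0)
    moved <- granges0(g$chrom[tgt], start, start + w, genome,
                      strand = as.character(BiocGenerics::strand(
                        repeats))[cand],
                      repeat_class = S4Vectors::mcols(
                        repeats)$repeat_class[cand],
                      repeat_family = S4Vectors::mcols(
                        repeats)$repeat_family[cand],
                      repeat_name = nm[cand])
    out <- suppressWarnings(c(repeats[-cand], moved))
    out <- BiocGenerics::sort(out, ignore.strand = TRUE)
    list(repeats = out,
         coupling = data.frame(element = cand, subfamily = nm[cand],
                               gene_id = g$gene_id[tgt]))
  })
}
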