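# Orchestration: a single config drives simulation, the ChIP island
# analyses and the expression analyses, writing one TSV per stage plus
# a YAML manifest. All randomness flows from one master seed through
# named substreams, so a rerun with the same config reproduces every
# output byte-identically.

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param outdir Output directory (NULL = in-memory only).
#' @return Nested list of stage parameters; serializable to YAML with
#'   [write_config()].
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulation = list(n_chroms = 3L, chrom_length = 2e6,
                      n_islands = 60L, island_width = 2500L,
                      enrichment_fold = 10, background_rate = 0.008,
                      attenuation_factor = 0.4,
                      attenuated_fraction = 0.5,
                      n_genes = 5000L,
                      stages = c("ESC", "EB_d6", "EB_d10"),
                      de_fraction = 0.05, accel_fraction = 0.1,
                      dispersion = 0.1, rna_depth = 2e5,
                      max_derepression_fold = 50,
                      read_length = 50L),
    islands = list(window_bp = 200L, gap_bp = 400L, fdr = 0.001,
                   fc_threshold = 1.5),
    repeats = list(n_draws = 10L),
    expression = list(fc = 2, fdr = 0.001, rpkm_min = 3,
                      rpbm_threshold = 0.003),
    accel = list(stage = "EB_d6", alphas = c(1.5, 2, 3, 4),
                 n_boot = 1000L, n_shuffles = 1000L),
    proximity = list(window_bp = 10000L))
}

#' Read / write a pipeline config as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Simulate the full synthetic dataset for a config
#'
#' Generates the genome, planted islands, repeat annotation (with the
#' planted de-repression fold ladder over all subfamilies), ChIP /
#' Input / RNA tracks and the expression time course. When
#' `config$outdir` is set, all inputs and truth tables are written
#' there (chrom sizes, BEDs, TSVs and a YAML manifest).
#'
#' @param config Config list from [default_config()].
#' @return List with all generated objects and the `truth` record.
#' @export
simulate_dataset <- function(config = default_config()) {
  sim <- config$simulation
  seed <- config$seed
  g <- generate_genome(sim$n_chroms, sim$chrom_length,
                       derive_seed(seed, "genome"))
  islands <- generate_planted_islands(g, sim$n_islands, sim$island_width,
                                      seed = derive_seed(seed, "islands"))
  rcfg <- default_repeat_config()
  repeats <- generate_repeat_annotation(g, rcfg, islands,
                                        derive_seed(seed, "repeats"))
  n_att <- round(sim$n_islands * sim$attenuated_fraction)
  att_idx <- with_seed(derive_seed(seed, "atten"),
                       sort(sample.int(sim$n_islands, n_att)))
  attenuation <- rep(1, sim$n_islands)
  attenuation[att_idx] <- sim$attenuation_factor
  chip <- generate_chip_tracks(g, islands, sim$enrichment_fold,
                               sim$background_rate, attenuation,
                               sim$read_length, derive_seed(seed, "chip"))
  # planted de-repression: a geometric fold ladder across subfamilies
  folds <- stats::setNames(
    2^seq(0, log2(sim$max_derepression_fold), length.out = nrow(rcfg)),
    rcfg$name)
  tc <- generate_expression_timecourse(
    sim$n_genes, sim$stages, sim$de_fraction, sim$accel_fraction,
    sim$dispersion, seed = derive_seed(seed, "expr"))
  models <- generate_gene_models(g, rownames(tc$em$counts),
                                 unname(tc$em$lengths))
  # couple strongly de-repressed elements to planted upregulated genes
  up_ids <- names(tc$truth$de_log2fc)[tc$truth$de_log2fc > 0]
  strong <- names(folds)[folds >= 10]
  cpl <- couple_elements_to_genes(repeats, strong, models, up_ids,
                                  seed = derive_seed(seed, "couple"))
  repeats <- cpl$repeats
  rna <- generate_rna_repeat_reads(g, repeats, folds, sim$rna_depth,
                                   sim$read_length,
                                   derive_seed(seed, "rna"))
  truth <- list(planted_islands = islands,
                attenuated_island_idx = att_idx,
                attenuation_factor = sim$attenuation_factor,
                enriched_subfamilies = rcfg$name[rcfg$co_placement > 0],
                co_placement = stats::setNames(rcfg$co_placement,
                                               rcfg$name),
                de_repressed_folds = folds,
                coupling = cpl$coupling,
                expression = tc$truth,
                seed = seed)
  data <- list(genome = g, planted_islands = islands, repeats = repeats,
               chip_ctrl = chip$chip_ctrl, chip_kd = chip$chip_kd,
               input = chip$input, rna_ctrl = rna$rna_ctrl,
               rna_kd = rna$rna_kd, em = tc$em, design = tc$design,
               models = models, truth = truth, config = config)
  if (!is.null(config$outdir)) write_dataset(data, config$outdir)
  data
}

# Write every simulated input (and truth) under outdir.
write_dataset <- function(data, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_chrom_sizes(data$genome, p("genome.chrom.sizes"))
  write_bed(data$planted_islands, p("planted_islands.bed"))
  write_repeat_bed(data$repeats, p("repeats.bed"))
  write_track_bed(data$chip_ctrl, p("chip_ctrl.bed"))
  write_track_bed(data$chip_kd, p("chip_kd.bed"))
  write_track_bed(data$input, p("input.bed"))
  write_track_bed(data$rna_ctrl, p("rna_ctrl.bed"))
  write_track_bed(data$rna_kd, p("rna_kd.bed"))
  write_counts_tsv(data$em, p("counts.tsv"))
  write_tsv(data$design, p("design.tsv"))
  tr <- data$truth
  write_tsv(data.frame(subfamily = names(tr$de_repressed_folds),
                       fold = unname(tr$de_repressed_folds)),
            p("truth_derepression.tsv"))
  write_tsv(data.frame(gene_id = tr$expression$de_gene_ids,
                       log2fc = unname(tr$expression$de_log2fc)),
            p("truth_de_genes.tsv"))
  write_tsv(data.frame(gene_id = tr$expression$accelerated_gene_ids),
            p("truth_accelerated_genes.tsv"))
  write_tsv(data.frame(island_idx = tr$attenuated_island_idx),
            p("truth_attenuated_islands.tsv"))
  write_tsv(tr$coupling, p("truth_coupling.tsv"))
  write_tsv(data$models$genes, p("gene_models.tsv"))
  yaml::write_yaml(data$config, p("manifest.yaml"))
  invisible(outdir)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = start0(gr), end = end0(gr),
             as.data.frame(S4Vectors::mcols(gr)), row.names = NULL)
}

#' Run the ChIP island analysis chain
#'
#' Islands are called on the control ChIP against Input, compared
#' between control and knockdown, overlapped with repeat labels,
#' tested for subfamily enrichment against matched random regions, and
#' profiled. One TSV per stage is written when `config$outdir` is set.
#'
#' @param config Config list.
#' @param data Optional pre-simulated dataset (default: simulate from
#'   the config).
#' @return List of stage results: `islands`, `differential`,
#'   `overlap_pct`, `enrichment` (per-class KS results),
#'   `enrichment_matrix`, `profile`, `fc_ecdf`.
#' @export
run_chip_analysis <- function(config = default_config(), data = NULL) {
  data <- data %||% simulate_dataset(config)
  ip <- config$islands
  islands <- call_islands(data$chip_ctrl, data$input,
                          ip$window_bp, ip$gap_bp, ip$fdr)
  if (length(islands) == 0) stop("no islands called on control ChIP")
  diff <- differential_islands(islands, data$chip_ctrl, data$chip_kd,
                               ip$fc_threshold, ip$fdr)
  ovl <- peak_overlap_percentage(islands, data$repeats, "family")
  rand <- sample_random_regions(islands, data$genome,
                                config$repeats$n_draws,
                                derive_seed(config$seed, "nullregions"))
  ks <- lapply(c("LINE", "LTR"), function(cls) {
    obs <- percent_coverage_per_island(islands, data$repeats, "class", cls)
    nul <- percent_coverage_per_island(rand, data$repeats, "class", cls)
    ecdf_ks_enrichment(obs, nul, level = "class", key = cls)
  })
  emat <- subfamily_enrichment_matrix(
    list(islands = islands), data$repeats, data$genome,
    config$repeats$n_draws, derive_seed(config$seed, "enrichmat"))
  prof <- average_profile(data$chip_ctrl, islands, 2000L, 40L)
  fce <- fold_change_ecdf(islands, data$chip_ctrl, data$chip_kd)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_tsv(granges_to_df(islands), p("islands.tsv"))
    write_tsv(granges_to_df(diff), p("differential_islands.tsv"))
    write_tsv(ovl, p("overlap_percentages.tsv"))
    write_tsv(do.call(rbind, lapply(ks, function(x)
      data.frame(level = x$level, key = x$key, D = x$ks_statistic,
                 p = x$ks_p_value, direction = x$direction))),
      p("enrichment_ks.tsv"))
    write_tsv(data.frame(subfamily = rownames(emat),
                         ratio = emat[, 1]), p("enrichment_matrix.tsv"))
    write_tsv(prof, p("profile.tsv"))
    write_tsv(data.frame(log2fc = fce$values, frac = fce$frac),
              p("fold_change_ecdf.tsv"))
  }
  list(islands = islands, differential = diff, overlap_pct = ovl,
       enrichment = ks, enrichment_matrix = emat, profile = prof,
       fc_ecdf = fce)
}

#' Run the expression analysis chain
#'
#' RPKM, DE genes (knockdown vs control at the ES stage), k-means and
#' PCA of the time course, the accelerated-differentiation ordering
#' statistic, repeat-element expression fold-changes, and the
#' element-to-gene proximity report.
#'
#' @inheritParams run_chip_analysis
#' @return List of stage results: `rpkm`, `de`, `kmeans`, `pca`,
#'   `acceleration`, `repeat_fc`, `expressed_elements`, `proximity`.
#' @export
run_expression_analysis <- function(config = default_config(),
                                    data = NULL) {
  data <- data %||% simulate_dataset(config)
  xp <- config$expression
  rpkm <- compute_rpkm(data$em)
  stages <- config$simulation$stages
  esc <- stages[1]
  de <- detect_de_genes(data$em, paste0("kd_", esc), paste0("ctrl_", esc),
                        xp$fc, xp$fdr, xp$rpkm_min)
  de_ids <- de$gene_id[de$is_de]
  km <- if (length(de_ids) >= 5)
    kmeans_time_course(rpkm[de_ids, , drop = FALSE],
                       k = min(20L, max(2L, length(de_ids) %/% 10)),
                       seed = derive_seed(config$seed, "kmeans")) else NULL
  pca <- pca_time_course(rpkm, data$design)
  accel <- accelerated_differentiation(
    rpkm, data$design, config$accel$stage, config$accel$alphas,
    config$accel$n_boot, config$accel$n_shuffles,
    derive_seed(config$seed, "accel"))
  rfc <- repeat_subfamily_fold_change(data$rna_ctrl, data$rna_kd,
                                      data$repeats, "name")
  rex <- repeat_expression(data$rna_kd, data$repeats)
  expressed <- filter_expressed_repeats(rex$elements, xp$rpbm_threshold)
  models <- data$models
  elements <- data$repeats[
    S4Vectors::mcols(data$repeats)$repeat_class == "LTR"]
  records <- elements_near_tss(elements, models,
                               config$proximity$window_bp)
  elem_fc <- element_fold_change(data$rna_ctrl, data$rna_kd, elements)
  prox <- proximity_expression_report(records, de, elem_fc)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_tsv(de, p("de_genes.tsv"))
    write_tsv(pca, p("pca.tsv"))
    write_tsv(accel, p("acceleration.tsv"))
    write_tsv(rfc, p("repeat_fold_change.tsv"))
    write_tsv(granges_to_df(expressed), p("expressed_elements.tsv"))
    write_tsv(records, p("proximity_records.tsv"))
    if (nrow(prox$per_gene)) write_tsv(prox$per_gene,
                                       p("proximity_per_gene.tsv"))
    if (!is.null(km))
      write_tsv(data.frame(gene_id = names(km$cluster),
                           cluster = unname(km$cluster)),
                p("kmeans_clusters.tsv"))
  }
  list(rpkm = rpkm, de = de, kmeans = km, pca = pca,
       acceleration = accel, repeat_fc = rfc,
       expressed_elements = expressed, proximity = prox)
}

# Per-element expression fold-change (knockdown over control) with a
# half-read pseudocount.
element_fold_change <- function(track_ctrl, track_kd, elements) {
  w <- BiocGenerics::width(elements)
  dc <- compute_rpbm(track_ctrl, elements)
  dk <- compute_rpbm(track_kd, elements)
  ec <- 0.5 / w / (track_ctrl$library_size / 1e6)
  ek <- 0.5 / w / (track_kd$library_size / 1e6)
  (dk + ek) / (dc + ec)
}

#' Run the full pipeline: simulate, ChIP analysis, expression analysis
#'
#' @param config Config list; set `config$outdir` to write every input
#'   and stage output plus the manifest.
#' @return List with `data`, `chip`, `expression`.
#' @export
run_all <- function(config = default_config()) {
  data <- simulate_dataset(config)
  chip <- run_chip_analysis(config, data)
  expr <- run_expression_analysis(config, data)
  list(data = data, chip = chip, expression = expr)
}
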