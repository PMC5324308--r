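# Relating repeat elements to genes: proximity to transcription start
# sites, genic-context annotation, and expression of elements near
# regulated genes. Gene and exon coordinates are held 0-based
# half-open, matching the interval convention.

#' Construct gene models from coordinate tables
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open span) and `strand` (`+`/`-`).
#' @param exons Optional data.frame with `gene_id`, `start`, `end`
#'   (0-based half-open, within the gene span).
#' @return Object of class `GeneModels`: the gene table with a computed
#'   `tss` column (span start on `+`, last base on `-`), plus the exon
#'   table.
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("genes needs columns: ", paste(need, collapse = ", "))
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (!is.null(exons)) {
    if (!all(c("gene_id", "start", "end") %in% names(exons)))
      stop("exons needs columns gene_id, start, end")
    if (!all(exons$gene_id %in% genes$gene_id))
      stop("exon refers to unknown gene")
    g <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < g$start | exons$end > g$end))
      stop("exon outside its gene span")
  }
  structure(list(genes = genes, exons = exons), class = "GeneModels")
}

#' Read gene models from a GTF file
#'
#' Uses `gene` and `exon` features; GTF 1-based closed coordinates are
#' converted to the internal 0-based half-open convention.
#' @param path GTF file.
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(S4Vectors::mcols(gr)$type)
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  g <- gr[type == "gene"]
  if (length(g) == 0) stop("no gene features in ", path)
  genes <- data.frame(gene_id = gid[type == "gene"],
                      chrom = as.character(GenomeInfoDb::seqnames(g)),
                      start = BiocGenerics::start(g) - 1L,
                      end = BiocGenerics::end(g),
                      strand = as.character(BiocGenerics::strand(g)))
  e <- gr[type == "exon"]
  exons <- if (length(e)) data.frame(
    gene_id = gid[type == "exon"],
    start = BiocGenerics::start(e) - 1L,
    end = BiocGenerics::end(e)) else NULL
  gene_models(genes, exons)
}

# GRanges of gene spans / exons from a GeneModels object.
gene_span_granges <- function(models) {
  granges0(models$genes$chrom, models$genes$start, models$genes$end,
           gene_id = models$genes$gene_id)
}
exon_granges <- function(models) {
  if (is.null(models$exons) || nrow(models$exons) == 0)
    return(granges0(character(), integer(), integer()))
  chrom <- models$genes$chrom[match(models$exons$gene_id,
                                    models$genes$gene_id)]
  granges0(chrom, models$exons$start, models$exons$end,
           gene_id = models$exons$gene_id)
}

#' Annotate the genic context of elements
#'
#' An element overlapping any exon of any gene is `exonic`; otherwise,
#' one overlapping any gene span is `intronic`; otherwise `intergenic`
#' (most-genic label wins when genes overlap).
#'
#' @param elements `GRanges` of elements.
#' @param models A `GeneModels` object.
#' @return Character vector of context labels, one per element.
#' @export
annotate_genic_context <- function(elements, models) {
  ctx <- rep("intergenic", length(elements))
  ctx[GenomicRanges::countOverlaps(
    elements, gene_span_granges(models), ignore.strand = TRUE) > 0] <-
    "intronic"
  ctx[GenomicRanges::countOverlaps(
    elements, exon_granges(models), ignore.strand = TRUE) > 0] <- "exonic"
  ctx
}

#' Elements within a window of gene transcription start sites
#'
#' An element qualifies for a gene when it intersects
#' `[TSS - window, TSS + window)`. Distance runs from the TSS to the
#' nearest element edge (0 when the element spans the TSS) and is
#' signed with upstream negative relative to the gene's strand.
#'
#' @param elements `GRanges` of elements (named via a `name` or
#'   `repeat_name` metadata column when available).
#' @param models A `GeneModels` object.
#' @param window_bp Window half-width in bp (default 10000).
#' @return data.frame with one row per (gene, element) pair: `gene_id`,
#'   `element`, `chrom`, `element_start`, `element_end`, `distance`,
#'   `context`.
#' @export
elements_near_tss <- function(elements, models, window_bp = 10000L) {
  if (window_bp <= 0) stop("window_bp must be positive")
  genes <- models$genes
  win <- granges0(genes$chrom, pmax(genes$tss - window_bp, 0),
                  genes$tss + window_bp)
  hits <- GenomicRanges::findOverlaps(win, elements, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  es <- start0(elements)[ei]
  ee <- end0(elements)[ei]
  tss <- genes$tss[gi]
  d <- ifelse(es > tss, es - tss,
              ifelse(ee <= tss, -(tss - (ee - 1)), 0))
  d <- ifelse(genes$strand[gi] == "-", -d, d)
  mc <- S4Vectors::mcols(elements)
  nm <- if ("repeat_name" %in% names(mc)) as.character(mc$repeat_name)
  else if ("name" %in% names(mc)) as.character(mc$name)
  else as.character(seq_along(elements))
  ctx <- annotate_genic_context(elements, models)
  data.frame(gene_id = genes$gene_id[gi],
             element = nm[ei], element_index = ei,
             chrom = as.character(GenomeInfoDb::seqnames(elements))[ei],
             element_start = es, element_end = ee,
             distance = d, context = ctx[ei], row.names = NULL)
}

#' Join element proximity, gene regulation and element/island changes
#'
#' For each upregulated gene (DE with positive log2 fold-change in the
#' knockdown-vs-control comparison), reports the number of nearby
#' elements, their mean expression fold-change, and (when islands are
#' supplied) the mean log2 fold-change of nearby islands. The summary
#' compares the element fold-change distribution near upregulated genes
#' with that near tested-but-unchanged genes by the KS enrichment test.
#'
#' @param records Proximity table from [elements_near_tss()] with
#'   `element_index` referring into the element set used below.
#' @param de_results DE table from [detect_de_genes()] with group A =
#'   knockdown, group B = control (so positive log2FC = upregulated in
#'   the knockdown).
#' @param element_fc Numeric vector of expression fold-changes, one per
#'   element of the proximity element set (knockdown over control).
#' @param islands Optional `GRanges` of differential islands carrying a
#'   `log2_fold_change` column.
#' @param models,window_bp Needed when `islands` is given, to find
#'   islands near each gene's TSS.
#' @return List with `per_gene` (data.frame over upregulated genes),
#'   `ks` (an `EnrichmentResult` or NULL), and counts
#'   `n_upregulated`, `n_unchanged`.
#' @export
proximity_expression_report <- function(records, de_results, element_fc,
                                        islands = NULL, models = NULL,
                                        window_bp = 10000L) {
  up_ids <- de_results$gene_id[de_results$is_de &
                                 de_results$log2_fold_change > 0]
  un_ids <- de_results$gene_id[!de_results$is_de]
  if (length(up_ids) == 0) {
    warning("no upregulated genes; empty report")
    return(list(per_gene = data.frame(), ks = NULL,
                n_upregulated = 0L, n_unchanged = length(un_ids)))
  }
  island_rec <- NULL
  if (!is.null(islands) && length(islands) > 0) {
    if (is.null(models)) stop("models required to relate islands to genes")
    island_rec <- elements_near_tss(islands, models, window_bp)
    island_rec$log2fc <- S4Vectors::mcols(islands)$log2_fold_change[
      island_rec$element_index]
  }
  per_gene <- do.call(rbind, lapply(up_ids, function(g) {
    r <- records[records$gene_id == g, , drop = FALSE]
    ifc <- if (!is.null(island_rec))
      island_rec$log2fc[island_rec$gene_id == g] else numeric(0)
    data.frame(gene_id = g, n_elements = nrow(r),
               mean_element_fc = if (nrow(r))
                 mean(element_fc[r$element_index]) else NA_real_,
               n_islands = length(ifc),
               mean_island_log2fc = if (length(ifc)) mean(ifc)
               else NA_real_)
  }))
  fc_up <- element_fc[records$element_index[records$gene_id %in% up_ids]]
  fc_un <- element_fc[records$element_index[records$gene_id %in% un_ids]]
  ks <- if (length(fc_up) && length(fc_un))
    ecdf_ks_enrichment(fc_up, fc_un, level = "proximity",
                       key = "element_fc_up_vs_unchanged") else NULL
  list(per_gene = per_gene, ks = ks,
       n_upregulated = length(up_ids), n_unchanged = length(un_ids))
}
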