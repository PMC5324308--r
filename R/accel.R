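# The "lagging gene" ordering statistic for knockdown differentiation
# time courses. Genes upregulated at least alpha-fold from the ES state
# to the control EB stage are selected; the observed quantity is the
# fraction of those genes whose knockdown EB expression falls strictly
# between the ES and control EB values (they "lag behind"). Bootstrap
# resampling of genes gives the error bar; independently permuting the
# three expression vectors over all genes and re-running the selection
# gives the chance expectation and its spread.

#' Bundle the three expression vectors for the ordering analysis
#'
#' @param esc RPKM in the control ES state, one value per gene.
#' @param eb_ctrl RPKM in the control EB at the analysed stage.
#' @param eb_kd RPKM in the knockdown EB at the same stage.
#' @param stage Stage label (metadata only).
#' @return Object of class `OrderingInput`.
#' @export
ordering_input <- function(esc, eb_ctrl, eb_kd, stage = "EB_d6") {
  esc <- as.numeric(esc)
  eb_ctrl <- as.numeric(eb_ctrl)
  eb_kd <- as.numeric(eb_kd)
  if (length(esc) != length(eb_ctrl) || length(esc) != length(eb_kd))
    stop("the three expression vectors must share one gene universe")
  if (any(c(esc, eb_ctrl, eb_kd) < 0))
    stop("expression values must be non-negative")
  structure(list(esc = esc, eb_ctrl = eb_ctrl, eb_kd = eb_kd,
                 stage = stage, n_genes = length(esc)),
            class = "OrderingInput")
}

#' Select genes regulated at least alpha-fold in the control cells
#'
#' With `direction = "up"`, selects genes with
#' `(eb_ctrl + eps) / (esc + eps) >= alpha`; with `"down"`, the
#' reciprocal ratio.
#'
#' @param input An `OrderingInput`.
#' @param alpha Fold threshold (>= 1).
#' @param pseudocount RPKM pseudocount (default 0.1).
#' @param direction `"up"` (ESC -> EB induction, default) or `"down"`.
#' @return Integer vector of selected gene indices.
#' @export
select_upregulated_genes <- function(input, alpha, pseudocount = 0.1,
                                     direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (alpha < 1) stop("alpha must be >= 1")
  r <- (input$eb_ctrl + pseudocount) / (input$esc + pseudocount)
  if (direction == "down") r <- 1 / r
  which(r >= alpha)
}

#' Fraction of selected genes that lag in the knockdown
#'
#' A gene lags when its knockdown EB value falls strictly between the
#' ES and control EB values: `eb_ctrl > eb_kd > esc` for upregulated
#' genes (reversed for downregulated). Ties fail the strict ordering.
#'
#' @param genes Non-empty integer vector of gene indices.
#' @param input An `OrderingInput`.
#' @param direction `"up"` or `"down"`.
#' @return Fraction in \[0, 1\].
#' @export
ordering_fraction <- function(genes, input, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(genes) == 0) stop("empty gene set: ordering fraction undefined")
  a <- input$esc[genes]
  b <- input$eb_kd[genes]
  c <- input$eb_ctrl[genes]
  if (direction == "up") mean(c > b & b > a) else mean(c < b & b < a)
}

#' Bootstrap standard error of the ordering fraction
#'
#' Genes are resampled with replacement `n_boot` times; the SE is the
#' standard deviation of the resampled fractions.
#'
#' @inheritParams ordering_fraction
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed.
#' @export
bootstrap_se <- function(genes, input, n_boot = 1000L, seed = 1L,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(genes) < 2) stop("need >= 2 genes to bootstrap")
  if (n_boot < 2) stop("n_boot must be >= 2")
  n <- length(genes)
  fr <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    ordering_fraction(genes[sample.int(n, n, replace = TRUE)], input,
                      direction)
  }, 0))
  stats::sd(fr)
}

#' Shuffle null for the ordering fraction
#'
#' Per replicate, the three expression vectors are permuted
#' independently over all genes; the alpha selection is re-applied on
#' the shuffled vectors (set `reselect = FALSE` to instead keep the
#' originally selected gene set and permute values within it) and the
#' ordering fraction recomputed. Replicates with an empty selection
#' are dropped; more than half dropped is an error.
#'
#' @param input An `OrderingInput`.
#' @param alpha Fold threshold (>= 1).
#' @param n_shuffles Number of shuffle replicates (>= 2).
#' @param seed Integer seed.
#' @param pseudocount RPKM pseudocount for the selection.
#' @param direction `"up"` or `"down"`.
#' @param reselect Re-apply the selection inside each replicate
#'   (default TRUE).
#' @return List with `expected_mean`, `expected_sd`, the per-replicate
#'   `fractions`, and `n_dropped`.
#' @export
shuffle_null <- function(input, alpha, n_shuffles = 1000L, seed = 1L,
                         pseudocount = 0.1, direction = c("up", "down"),
                         reselect = TRUE) {
  direction <- match.arg(direction)
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  n <- input$n_genes
  fixed <- if (!reselect)
    select_upregulated_genes(input, alpha, pseudocount, direction)
  fr <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    if (reselect) {
      sh <- ordering_input(sample(input$esc), sample(input$eb_ctrl),
                           sample(input$eb_kd), input$stage)
      sel <- select_upregulated_genes(sh, alpha, pseudocount, direction)
      if (length(sel) == 0) return(NA_real_)
      ordering_fraction(sel, sh, direction)
    } else {
      if (length(fixed) == 0) return(NA_real_)
      k <- length(fixed)
      sh <- ordering_input(sample(input$esc[fixed]),
                           sample(input$eb_ctrl[fixed]),
                           sample(input$eb_kd[fixed]), input$stage)
      ordering_fraction(seq_len(k), sh, direction)
    }
  }, 0))
  dropped <- sum(is.na(fr))
  if (dropped > n_shuffles / 2)
    stop("shuffled selection empty in more than half the replicates")
  fr <- fr[!is.na(fr)]
  list(expected_mean = mean(fr), expected_sd = stats::sd(fr),
       fractions = fr, n_dropped = dropped)
}

#' Compare the observed ordering fraction with its shuffle null
#'
#' @param observed_fraction Observed lagging fraction.
#' @param null Result of [shuffle_null()].
#' @return List with `z_score`, `empirical_p` (two-sided with +1
#'   smoothing over the shuffle replicates) and `verdict` in
#'   `{lagging_fewer_than_expected, consistent_with_chance,
#'   lagging_more_than_expected}` (|z| >= 2 rule).
#' @export
acceleration_test <- function(observed_fraction, null) {
  if (!is.finite(null$expected_sd) || null$expected_sd == 0)
    stop("expected_sd is zero: null is degenerate")
  z <- (observed_fraction - null$expected_mean) / null$expected_sd
  dev <- abs(null$fractions - null$expected_mean)
  p <- (1 + sum(dev >= abs(observed_fraction - null$expected_mean))) /
    (length(null$fractions) + 1)
  verdict <- if (z <= -2) "lagging_fewer_than_expected" else
    if (z >= 2) "lagging_more_than_expected" else "consistent_with_chance"
  list(z_score = z, empirical_p = p, verdict = verdict)
}

#' Full accelerated-differentiation analysis over a grid of alphas
#'
#' Builds the three-vector input from an RPKM matrix and design
#' (averaging replicate samples per condition), then runs selection,
#' ordering fraction, bootstrap and shuffle null at each alpha.
#'
#' @param rpkm RPKM matrix (genes x samples).
#' @param design Design data.frame (`sample_id`, `genotype`, `stage`);
#'   genotypes must include `control` and `knockdown`; the first stage
#'   is taken as the ES state.
#' @param stage EB stage to analyse (e.g. `"EB_d6"`).
#' @param alphas Fold thresholds (default `c(1.5, 2, 3, 4)`).
#' @param n_boot,n_shuffles Replicates (defaults 1000).
#' @param seed Integer seed.
#' @param direction `"up"` or `"down"`.
#' @param pseudocount RPKM pseudocount.
#' @return data.frame with one row per alpha: `stage`, `alpha`,
#'   `n_genes`, `observed_fraction`, `bootstrap_se`, `expected_mean`,
#'   `expected_sd`, `z_score`, `empirical_p`, `verdict`.
#' @export
accelerated_differentiation <- function(rpkm, design, stage,
                                        alphas = c(1.5, 2, 3, 4),
                                        n_boot = 1000L, n_shuffles = 1000L,
                                        seed = 1L,
                                        direction = c("up", "down"),
                                        pseudocount = 0.1) {
  direction <- match.arg(direction)
  esc_stage <- design$stage[1]
  pick <- function(genotype, stg) {
    ids <- design$sample_id[design$genotype == genotype &
                              design$stage == stg]
    if (length(ids) == 0)
      stop("no samples for ", genotype, " / ", stg)
    rowMeans(rpkm[, ids, drop = FALSE])
  }
  input <- ordering_input(pick("control", esc_stage),
                          pick("control", stage),
                          pick("knockdown", stage), stage)
  rows <- lapply(seq_along(alphas), function(i) {
    alpha <- alphas[i]
    genes <- select_upregulated_genes(input, alpha, pseudocount, direction)
    if (length(genes) < 2)
      stop("fewer than 2 genes selected at alpha = ", alpha)
    obs <- ordering_fraction(genes, input, direction)
    se <- bootstrap_se(genes, input, n_boot,
                       derive_seed(seed, paste0("boot", i)), direction)
    nul <- shuffle_null(input, alpha, n_shuffles,
                        derive_seed(seed, paste0("shuf", i)),
                        pseudocount, direction)
    tst <- acceleration_test(obs, nul)
    data.frame(stage = stage, alpha = alpha, n_genes = length(genes),
               observed_fraction = obs, bootstrap_se = se,
               expected_mean = nul$expected_mean,
               expected_sd = nul$expected_sd,
               z_score = tst$z_score, empirical_p = tst$empirical_p,
               verdict = tst$verdict)
  })
  do.call(rbind, rows)
}
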