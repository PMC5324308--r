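# Independent brute-force oracles. These deliberately avoid the code
# paths of the package: per-base marking, all-pairs scans and explicit
# enumeration, so implementation and oracle can only agree if both are
# right.

# Fraction of [qs, qe) covered by the union of subject intervals, by
# marking every base.
oracle_overlap_fraction <- function(qs, qe, ss, se) {
  bases <- qs:(qe - 1)
  covered <- rep(FALSE, length(bases))
  for (i in seq_along(ss))
    covered <- covered | (bases >= ss[i] & bases < se[i])
  mean(covered)
}

# Percentage of A intervals overlapping >= min_bp bases of any B, by
# quadratic all-pairs scan.
oracle_overlap_percent <- function(as, ae, bs, be, min_bp = 1) {
  hit <- vapply(seq_along(as), function(i) {
    any(pmin(ae[i], be) - pmax(as[i], bs) >= min_bp)
  }, TRUE)
  100 * mean(hit)
}

# Reads (0-based starts, fixed length) overlapping [s, e), linear scan.
oracle_count_reads <- function(pos, read_length, s, e) {
  sum(pos + read_length > s & pos < e)
}

# Two-sample KS statistic: sup over all pooled points of the ECDF gap.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), 0)
  fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(fx - fy))
}

# Ordering predicate checked gene by gene.
oracle_ordering_fraction <- function(esc, eb_ctrl, eb_kd) {
  ok <- 0
  for (i in seq_along(esc))
    if (eb_ctrl[i] > eb_kd[i] && eb_kd[i] > esc[i]) ok <- ok + 1
  ok / length(esc)
}

# Independent re-implementation of the shuffle null (plain loop,
# explicit permutation indices).
oracle_shuffle_mean <- function(esc, eb_ctrl, eb_kd, alpha, n_rep, seed,
                                pseudocount = 0.1) {
  set.seed(seed)
  n <- length(esc)
  fr <- numeric(0)
  for (r in seq_len(n_rep)) {
    a <- esc[sample.int(n)]
    c <- eb_ctrl[sample.int(n)]
    b <- eb_kd[sample.int(n)]
    sel <- which((c + pseudocount) / (a + pseudocount) >= alpha)
    if (length(sel) == 0) next
    fr <- c(fr, oracle_ordering_fraction(a[sel], c[sel], b[sel]))
  }
  fr
}

# Random non-degenerate interval set on a toy genome (plain base R).
rand_intervals0 <- function(n, chrom_len, max_len = 200) {
  s <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1
  w <- sample.int(max_len, n, replace = TRUE)
  list(start = s, end = s + w)
}

# Jaccard index of two intervals on the same chromosome.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}
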