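toy_repeats <- function(g) {
  gr <- GRanges(rep("chr1", 4),
                IRanges::IRanges(c(11, 31, 101, 201),
                                 c(20, 50, 150, 220)))  # 0-based [10,20)...
  GenomeInfoDb::seqinfo(gr) <- g
  repeat_annotation(gr,
                    repeat_class = c("LINE", "LINE", "LTR", "LTR"),
                    repeat_family = c("L1", "L1", "ERVK", "ERVK"),
                    repeat_name = c("L1A", "L1B", "IAP1", "IAP1"))
}

test_that("repeat annotation enforces a functional hierarchy", {
  gr <- GRanges("chr1", IRanges::IRanges(c(1, 11), c(5, 15)))
  expect_error(repeat_annotation(gr, c("LINE", "LTR"), c("L1", "L1"),
                                 c("a", "b")), "family")
  expect_error(repeat_annotation(gr, c("LINE", "LINE"), c("L1", "ERVK"),
                                 c("a", "a")), "name")
})

test_that("per-island repeat coverage matches the base-marking oracle", {
  g <- make_genome("chr1", 1e4)
  rep_ann <- toy_repeats(g)
  island <- GRanges("chr1", IRanges::IRanges(1, 100))  # [0,100)
  GenomeInfoDb::seqinfo(island) <- g
  # repeats of the L1 family at [10,20) and [30,50): 30 of 100 bases
  expect_equal(percent_coverage_per_island(island, rep_ann, "family", "L1"),
               0.30)
  expect_equal(percent_coverage_per_island(island, rep_ann, "name", "IAP1"),
               0)
  expect_error(percent_coverage_per_island(island, rep_ann, "name", "nope"),
               "available")
  set.seed(17)
  for (rep in 1:30) {
    iv <- rand_intervals0(5, 5000, 300)
    isl <- GRanges("chr1", IRanges::IRanges(iv$start + 1, iv$end))
    rp <- rand_intervals0(20, 5000, 200)
    ann <- repeat_annotation(
      GRanges("chr1", IRanges::IRanges(rp$start + 1, rp$end)),
      rep("LINE", 20), rep("L1", 20), rep("L1X", 20))
    got <- percent_coverage_per_island(isl, ann, "name", "L1X")
    want <- vapply(1:5, function(i)
      oracle_overlap_fraction(iv$start[i], iv$end[i], rp$start, rp$end), 0)
    expect_equal(got, want)
  }
})

test_that("KS enrichment matches examples and the sup-gap oracle", {
  r0 <- ecdf_ks_enrichment(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$ks_statistic, 0)
  expect_equal(r0$ks_p_value, 1)
  expect_equal(r0$direction, "none")
  r1 <- ecdf_ks_enrichment(c(0.6, 0.7, 0.8), c(0.1, 0.2, 0.3))
  expect_equal(r1$ks_statistic, 1)
  expect_equal(r1$direction, "enriched")
  r2 <- ecdf_ks_enrichment(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(r2$ks_statistic,
               oracle_ks_D(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3)))
  expect_error(ecdf_ks_enrichment(numeric(0), 1), "non-empty")
  set.seed(23)
  for (rep in 1:300) {
    x <- runif(sample(3:30, 1))
    y <- runif(sample(3:30, 1))
    expect_equal(ecdf_ks_enrichment(x, y)$ks_statistic, oracle_ks_D(x, y),
                 tolerance = 1e-12)
  }
})

test_that("peak overlap percentages follow the all-pairs oracle", {
  g <- make_genome("chr1", 1e4)
  rep_ann <- toy_repeats(g)
  islands <- GRanges("chr1", IRanges::IRanges(c(1, 1001, 2001, 41),
                                              width = 30))
  GenomeInfoDb::seqinfo(islands) <- g
  tab <- peak_overlap_percentage(islands, rep_ann, "family")
  # islands [0,30) and [40,70) overlap L1 elements; the other two do not
  expect_equal(tab$percent_overlap[tab$key == "L1"], 50)
  expect_equal(tab$percent_overlap[tab$key == "ERVK"], 0)
  expect_true(all(diff(tab$percent_overlap) <= 0))
})

test_that("subfamily enrichment ratios separate planted from uniform", {
  g <- make_genome(c("chr1", "chr2"), c(2e6, 2e6))
  isl <- generate_planted_islands(g, 40, 1000, seed = 5)
  cfg <- data.frame(name = c("planted_syn", "uniform_syn"),
                    family = c("ERVK", "L1"), class = c("LTR", "LINE"),
                    count = c(60, 400), length = c(400, 200),
                    co_placement = c(0.8, 0))
  ann <- generate_repeat_annotation(g, cfg, isl, seed = 9)
  m <- subfamily_enrichment_matrix(list(isl = isl), ann, g,
                                   n_draws = 10, seed = 3)
  expect_gte(m["planted_syn", "isl"], 10)
  expect_true(m["uniform_syn", "isl"] >= 0.3 &&
                m["uniform_syn", "isl"] <= 3)
  # an island set identical to the element set: observed overlap 100%
  sub <- ann[S4Vectors::mcols(ann)$repeat_name == "uniform_syn"]
  m2 <- subfamily_enrichment_matrix(list(self = sub), ann, g,
                                    n_draws = 2, seed = 4)
  expect_equal(attr(m2, "observed")["uniform_syn", "self"], 100)
})

test_that("enrichment D grows monotonically with planted co-placement", {
  g <- make_genome("chr1", 2e6)
  isl <- generate_planted_islands(g, 40, 1000, seed = 6)
  co <- seq(0, 0.9, length.out = 6)
  D <- vapply(seq_along(co), function(i) {
    cfg <- data.frame(name = "sweep_syn", family = "ERVK", class = "LTR",
                      count = 80, length = 400, co_placement = co[i])
    ann <- generate_repeat_annotation(g, cfg, isl, seed = 100 + i)
    obs <- percent_coverage_per_island(isl, ann, "name", "sweep_syn")
    rand <- sample_random_regions(isl, g, 10, seed = 200 + i)
    nul <- percent_coverage_per_island(rand, ann, "name", "sweep_syn")
    ecdf_ks_enrichment(obs, nul)$ks_statistic
  }, 0)
  expect_gt(cor(co, D, method = "spearman"), 0.9)
})

test_that("RepeatMasker .out tables parse into the hierarchy", {
  lines <- c("   SW  perc perc perc  query     position in query",
             "score  div. del. ins.  sequence  begin end (left)",
             "",
             "  463 1.3 0.6 1.7 chr1 1001 1500 (0) + L1Md_T LINE/L1 1 500 (0) 1",
             "  240 2.0 0.1 0.2 chr1 3001 3400 (0) C IAPLTR2 LTR/ERVK 1 400 (0) 2")
  f <- withr::local_tempfile(lines = lines)
  ann <- read_repeatmasker_out(f)
  expect_length(ann, 2)
  expect_equal(start(ann), c(1001, 3001))  # 1-based closed kept
  expect_equal(S4Vectors::mcols(ann)$repeat_class, c("LINE", "LTR"))
  expect_equal(S4Vectors::mcols(ann)$repeat_family, c("L1", "ERVK"))
  expect_equal(S4Vectors::mcols(ann)$repeat_name, c("L1Md_T", "IAPLTR2"))
})

test_that("repeat BED6+3 files round-trip", {
  g <- make_genome("chr1", 1e4)
  ann <- toy_repeats(g)
  f <- withr::local_tempfile()
  write_repeat_bed(ann, f)
  back <- read_repeat_bed(f, g)
  expect_equal(start(back), start(ann))
  expect_equal(S4Vectors::mcols(back)$repeat_name,
               S4Vectors::mcols(ann)$repeat_name)
})
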