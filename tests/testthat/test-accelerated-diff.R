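test_that("alpha selection follows the fold rule with pseudocount", {
  inp <- ordering_input(esc = c(1, 4, 2), eb_ctrl = c(4, 1, 2),
                        eb_kd = c(2, 2, 2))
  expect_equal(select_upregulated_genes(inp, 2), 1L)
  # alpha = 1 keeps every gene with eb_ctrl >= esc (boundary inclusive)
  expect_equal(select_upregulated_genes(inp, 1), c(1L, 3L))
  expect_error(select_upregulated_genes(inp, 0.5), "alpha")
  # the downregulated variant mirrors the selection
  expect_equal(select_upregulated_genes(inp, 2, direction = "down"), 2L)
})

test_that("selected-set size is non-increasing in alpha", {
  set.seed(3)
  inp <- ordering_input(rlnorm(500, 1, 1), rlnorm(500, 1.5, 1),
                        rlnorm(500, 1.2, 1))
  sizes <- vapply(c(1, 1.5, 2, 3, 4, 8),
                  function(a) length(select_upregulated_genes(inp, a)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("ordering fraction counts strict orderings only", {
  # triples (esc, eb_kd, eb_ctrl): only the first satisfies 5 > 3 > 1
  inp <- ordering_input(esc = c(1, 1, 3), eb_ctrl = c(5, 5, 2),
                        eb_kd = c(3, 6, 1))
  expect_equal(ordering_fraction(1:3, inp), 1 / 3)
  # ties fail the strict predicate
  tie <- ordering_input(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(ordering_fraction(1:2, tie), 0)
  expect_error(ordering_fraction(integer(0), inp), "empty")
  # brute-force oracle on random instances
  set.seed(29)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    a <- runif(n); b <- runif(n); c <- runif(n)
    oi <- ordering_input(a, c, b)
    expect_equal(ordering_fraction(seq_len(n), oi),
                 oracle_ordering_fraction(a, c, b))
  }
})

test_that("ordering fraction is invariant to common monotone transforms", {
  set.seed(37)
  a <- rlnorm(300); b <- rlnorm(300); c <- rlnorm(300)
  f0 <- ordering_fraction(1:300, ordering_input(a, c, b))
  for (tf in list(function(x) x^3, exp, function(x) 5 * x + 2)) {
    ft <- ordering_fraction(1:300, ordering_input(tf(a), tf(c), tf(b)))
    expect_equal(ft, f0)
  }
})

test_that("bootstrap SE matches the binomial closed form", {
  # degenerate: every gene satisfies the ordering
  inp1 <- ordering_input(esc = rep(1, 10), eb_ctrl = rep(9, 10),
                         eb_kd = rep(5, 10))
  expect_equal(bootstrap_se(1:10, inp1, n_boot = 100, seed = 1), 0)
  # SE within 20% of sqrt(f(1-f)/n) at n = 500, f ~ 0.3
  set.seed(43)
  n <- 500
  lag <- rbinom(n, 1, 0.3) == 1
  esc <- rep(1, n)
  eb_ctrl <- rep(9, n)
  eb_kd <- ifelse(lag, 5, 11)  # 9 > 5 > 1 lags; 11 breaks the order
  inp <- ordering_input(esc, eb_ctrl, eb_kd)
  f <- ordering_fraction(1:n, inp)
  se <- bootstrap_se(1:n, inp, n_boot = 2000, seed = 7)
  expect_lt(abs(se - sqrt(f * (1 - f) / n)) / sqrt(f * (1 - f) / n), 0.2)
  # seeded determinism
  expect_identical(se, bootstrap_se(1:n, inp, n_boot = 2000, seed = 7))
  expect_error(bootstrap_se(1L, inp, 100, 1), ">= 2")
})

test_that("shuffle null gives the analytic conditional mean for iid data", {
  # with iid continuous vectors and alpha = 1, selection keeps the 3 of
  # 6 orderings with eb_ctrl >= esc; exactly 1 of those 3 lags, so the
  # conditional expectation is 1/3
  oi <- generate_ordering_input(5000, 0, seed = 5)
  nul <- shuffle_null(oi$input, alpha = 1, n_shuffles = 400, seed = 6)
  expect_lt(abs(nul$expected_mean - 1 / 3), 0.02)
  # determinism
  nul2 <- shuffle_null(oi$input, alpha = 1, n_shuffles = 400, seed = 6)
  expect_identical(nul[c("expected_mean", "expected_sd")],
                   nul2[c("expected_mean", "expected_sd")])
  # constant vectors: every shuffled replicate is all ties
  cst <- ordering_input(rep(2, 50), rep(2, 50), rep(2, 50))
  nc <- shuffle_null(cst, 1, 50, seed = 1)
  expect_equal(nc$expected_mean, 0)
})

test_that("shuffle null agrees with an independent re-implementation", {
  set.seed(47)
  a <- rlnorm(8, 1, 1); c <- rlnorm(8, 1.5, 1); b <- rlnorm(8, 1, 1)
  inp <- ordering_input(a, c, b)
  n_rep <- 20000
  mine <- shuffle_null(inp, alpha = 1.5, n_shuffles = n_rep, seed = 9)
  other <- oracle_shuffle_mean(a, c, b, alpha = 1.5, n_rep = n_rep,
                               seed = 1009)
  se <- sqrt(mine$expected_sd^2 / length(mine$fractions) +
               var(other) / length(other))
  expect_lt(abs(mine$expected_mean - mean(other)), 3 * se)
})

test_that("the within-selection shuffle variant is available", {
  oi <- generate_ordering_input(2000, 0, seed = 15)
  nul <- shuffle_null(oi$input, alpha = 2, n_shuffles = 200, seed = 16,
                      reselect = FALSE)
  expect_true(is.finite(nul$expected_mean))
  expect_equal(nul$n_dropped, 0)
})

test_that("acceleration verdicts separate planted effects from chance", {
  # planted acceleration: knockdown drawn ahead of the control
  # trajectory for 30% of genes depresses the lagging fraction
  verdicts_null <- verdicts_accel <- character(8)
  for (s in 1:8) {
    o0 <- generate_ordering_input(3000, 0, seed = 500 + s)
    g0 <- select_upregulated_genes(o0$input, 2)
    t0 <- acceleration_test(
      ordering_fraction(g0, o0$input),
      shuffle_null(o0$input, 2, 300, seed = 600 + s))
    verdicts_null[s] <- t0$verdict
    o3 <- generate_ordering_input(3000, 0.3, seed = 700 + s)
    g3 <- select_upregulated_genes(o3$input, 2)
    t3 <- acceleration_test(
      ordering_fraction(g3, o3$input),
      shuffle_null(o3$input, 2, 300, seed = 800 + s))
    verdicts_accel[s] <- t3$verdict
  }
  expect_gte(sum(verdicts_null == "consistent_with_chance"), 7)
  expect_gte(sum(verdicts_accel == "lagging_fewer_than_expected"), 7)
})

test_that("acceleration test handles boundary and degenerate cases", {
  nul <- list(expected_mean = 0.3, expected_sd = 0.02,
              fractions = c(0.28, 0.3, 0.32, 0.3))
  t0 <- acceleration_test(0.3, nul)
  expect_equal(t0$z_score, 0)
  expect_equal(t0$verdict, "consistent_with_chance")
  nul0 <- list(expected_mean = 0, expected_sd = 0, fractions = rep(0, 5))
  expect_error(acceleration_test(0.1, nul0), "degenerate")
})

test_that("the full analysis runs over an alpha grid from a design", {
  tc <- generate_expression_timecourse(n_genes = 1500, seed = 77)
  rpkm <- compute_rpkm(tc$em)
  res <- accelerated_differentiation(rpkm, tc$design, "EB_d6",
                                     alphas = c(1.5, 2, 3),
                                     n_boot = 100, n_shuffles = 100,
                                     seed = 78)
  expect_equal(nrow(res), 3)
  expect_true(all(diff(res$n_genes) <= 0))
  expect_true(all(res$observed_fraction >= 0 &
                    res$observed_fraction <= 1))
  expect_true(all(res$empirical_p > 0 & res$empirical_p <= 1))
  # deterministic given the seed
  res2 <- accelerated_differentiation(rpkm, tc$design, "EB_d6",
                                      alphas = c(1.5, 2, 3),
                                      n_boot = 100, n_shuffles = 100,
                                      seed = 78)
  expect_identical(res, res2)
})
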