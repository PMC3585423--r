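test_that("TMM factors are 1 for identical or purely rescaled libraries", {
  a <- random_table(100, 1, 1)[, 1]
  counts <- cbind(s1 = a, s2 = a)
  expect_equal(unname(as.numeric(tmm_factors(counts))), c(1, 1))
  counts2 <- cbind(s1 = a, s2 = 2 * a)
  expect_equal(unname(as.numeric(tmm_factors(counts2))), c(1, 1))
})

test_that("TMM matches the brute-force oracle and shifts against an inflated gene", {
  for (sd in 1:5) {
    counts <- random_table(50, 4, sd)
    counts <- counts[rowSums(counts) > 0, ]
    got <- tmm_factors(counts)
    ref <- attr(got, "ref_sample")
    expect_equal(unname(as.numeric(got)), oracle_tmm(counts, ref), tolerance = 1e-10)
  }
  a <- random_table(60, 1, 9)[, 1] + 1
  b <- a
  b[1] <- 100 * a[1] # composition outlier in sample 2
  counts <- cbind(s1 = a, s2 = b)
  got <- as.numeric(tmm_factors(counts, ref_sample = 1))
  orc <- oracle_tmm(counts, 1)
  expect_equal(unname(got), orc, tolerance = 1e-10)
  # the outlier inflates library 2's size, so its factor moves the same
  # direction as the oracle's (away from 1)
  expect_equal(sign(log(got[2])), sign(log(orc[2])))
  expect_gt(abs(log(orc[2])), 0)
})

test_that("TMM fails loudly when trimming leaves fewer than 2 genes", {
  counts <- cbind(s1 = c(5, 0, 0), s2 = c(7, 3, 2))
  expect_error(tmm_factors(counts), class = "mirsat_tmm_degenerate")
})

test_that("median-of-ratios size factors match oracle and DESeq2", {
  one <- matrix(c(4, 8, 2), ncol = 1, dimnames = list(NULL, "s1"))
  expect_equal(unname(as.numeric(median_ratio_size_factors(one))), 1)

  a <- random_table(50, 1, 2)[, 1] + 1
  counts <- cbind(s1 = a, s2 = 2 * a)
  sf <- as.numeric(median_ratio_size_factors(counts))
  expect_equal(sf[2] / sf[1], 2)

  for (sd in 1:5) {
    counts <- random_table(50, 5, 10 + sd) + 1
    got <- as.numeric(median_ratio_size_factors(counts))
    expect_equal(got, unname(oracle_median_ratio(counts)), tolerance = 1e-10)
    # DESeq2 takes the median on the log scale, which differs from the
    # ratio-scale median only in how the two middle genes are averaged
    ds <- DESeq2::estimateSizeFactorsForMatrix(counts)
    expect_equal(got, unname(ds), tolerance = 1e-3)
  }

  allzero <- cbind(s1 = c(0, 5), s2 = c(3, 0))
  expect_error(median_ratio_size_factors(allzero), class = "mirsat_no_common_genes")
})

test_that("common dispersion is 0 for constant counts and ~0 for Poisson data", {
  counts <- cbind(a1 = c(5, 9), a2 = c(5, 9), b1 = c(7, 2), b2 = c(7, 2))
  groups <- factor(c("a", "a", "b", "b"))
  expect_equal(estimate_common_dispersion(counts, groups), 0)

  phis <- vapply(1:10, function(sd) {
    sim <- withr::with_seed(sd, {
      mu <- exp(rnorm(500, 4, 1))
      matrix(rpois(500 * 8, rep(mu, 8)), nrow = 500)
    })
    estimate_common_dispersion(sim, factor(rep(c("a", "b"), each = 4)))
  }, numeric(1))
  expect_lt(mean(phis), 0.01)

  expect_error(
    estimate_common_dispersion(cbind(a = c(1, 2), b = c(3, 4)), factor(c("a", "b"))),
    class = "mirsat_no_replicates"
  )
})

test_that("common dispersion recovers the simulated truth", {
  phis <- vapply(1:20, function(sd) {
    sim <- withr::with_seed(sd, {
      mu <- exp(rnorm(500, 4.5, 1))
      matrix(rnbinom(500 * 18, mu = rep(mu, 18), size = 1 / 0.2), nrow = 500)
    })
    estimate_common_dispersion(sim, factor(rep(c("a", "b"), each = 9)))
  }, numeric(1))
  expect_equal(mean(phis), 0.2, tolerance = 0.25) # within +/- 0.05 absolute
  expect_true(abs(mean(phis) - 0.2) < 0.05)
})

test_that("the exact test is symmetric, null-calibrated and matches enumeration", {
  counts <- matrix(c(10, 10, 10, 10), nrow = 1,
                   dimnames = list("m1", paste0("s", 1:4)))
  groups <- factor(c("a", "a", "b", "b"))
  eq <- nb_exact_test(counts, groups, phi = 0, effective_sizes = rep(100, 4))
  expect_equal(eq$pvalue, 1)
  expect_equal(eq$log2fc, 0)

  # swapping group labels negates log2FC and keeps p
  set.seed(3)
  counts2 <- matrix(rpois(40, 20), nrow = 10,
                    dimnames = list(paste0("m", 1:10), paste0("s", 1:4)))
  f1 <- nb_exact_test(counts2, groups, 0.1, rep(500, 4))
  f2 <- nb_exact_test(counts2, factor(c("a", "a", "b", "b"), levels = c("b", "a")),
                      0.1, rep(500, 4))
  expect_equal(f1$pvalue, f2$pvalue, tolerance = 1e-12)
  expect_equal(f1$log2fc, -f2$log2fc, tolerance = 1e-12)

  # phi = 0, totals 10 vs 0 with equal sizes: exact binomial two-sided
  # probability by enumeration
  c10 <- matrix(c(10, 0), nrow = 1, dimnames = list("m1", c("s1", "s2")))
  got <- nb_exact_test(c10, factor(c("a", "b")), phi = 0,
                       effective_sizes = c(1000, 1000))$pvalue
  probs <- vapply(0:10, function(k) choose(10, k) * 0.5^10, numeric(1))
  expect_equal(got, sum(probs[probs <= probs[11] + 1e-15]))
  expect_equal(got, 2 / 1024)

  # phi > 0: conditional law by direct enumeration at an arbitrary success
  # probability (the conditional distribution must not depend on it)
  phi <- 0.5; n1 <- 2; n2 <- 2; s1 <- 6; s2 <- 1; t <- s1 + s2
  for (q in c(0.2, 0.7)) {
    pr <- dnbinom(0:t, size = n1 / phi, prob = q) *
      dnbinom(t:0, size = n2 / phi, prob = q)
    pr <- pr / sum(pr)
    orc <- sum(pr[pr <= pr[s1 + 1] * (1 + 1e-10)])
    cm <- matrix(c(3, 3, 1, 0), nrow = 1, dimnames = list("m1", paste0("s", 1:4)))
    got <- nb_exact_test(cm, factor(c("a", "a", "b", "b")), phi,
                         effective_sizes = rep(100, 4))$pvalue
    expect_equal(got, orc, tolerance = 1e-10)
  }

  expect_error(
    nb_exact_test(matrix(c(1.5, 2), nrow = 1), factor(c("a", "b")), 0),
    class = "mirsat_noninteger_counts"
  )
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mirsat_bad_pvalues")

  # step-up oracle, order preserved
  set.seed(8)
  p <- runif(30)
  o <- order(p)
  m <- length(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- pmin(1, adj_sorted)[order(o)]
  got <- bh_adjust(p)
  expect_equal(got, oracle)
  expect_true(all(got >= p))
})

test_that("group_t_test matches the closed form and handles degenerate input", {
  same <- c(1, 2, 3)
  r <- group_t_test(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  sep <- group_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(sep$p_value, 1e-6)

  # textbook Welch case, closed form coded out
  a <- c(27.1, 22.0, 20.8, 23.4, 23.4)
  b <- c(19.7, 20.4, 19.6, 17.8, 18.6)
  r <- group_t_test(a, b, "welch")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(r$statistic, tstat)
  expect_equal(r$df, df)
  expect_equal(r$p_value, 2 * stats::pt(-abs(tstat), df))

  rp <- group_t_test(a, b, "pooled")
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  tp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(rp$statistic, tp)
  expect_equal(rp$df, 8)

  expect_message(cc <- group_t_test(c(2, 2), c(2, 2)), "constant")
  expect_equal(cc$p_value, 1)
  expect_equal(group_t_test(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("the full DE wrapper flags injected signal and orders by padj", {
  ref <- build_reference(120, seed = 55)
  prof <- simulate_abundances(ref, seed = 56)
  strong <- names(sort(prof, decreasing = TRUE))[3]
  tr <- experiment_truth(ref, setNames(3, strong), phi = 0.05, n_per_group = 6)
  sim <- simulate_experiment_counts(ref, prof, tr, depth = 20000, seed = 57)
  de <- de_exact_test(sim$counts, sim$groups)
  expect_s3_class(de$table, "tbl_df")
  expect_true(all(de$table$padj >= de$table$pvalue - 1e-15))
  expect_identical(de$table$significant, de$table$padj <= 0.05)
  expect_true(all(diff(de$table$padj) >= 0))
  expect_true(strong %in% de$table$mirna_id[de$table$significant])
  expect_gt(de$table$log2fc[de$table$mirna_id == strong], 1)
})
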