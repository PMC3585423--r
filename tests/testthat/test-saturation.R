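test_that("subsampling returns the pool at full depth and nothing at zero", {
  pool <- collapse_reads(rep(c("AAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCC"), c(3, 1)))
  full <- subsample_reads(pool, 4, seed = 1)
  expect_equal(setNames(full$count, full$sequence), setNames(pool$count, pool$sequence))
  expect_equal(nrow(subsample_reads(pool, 0, seed = 1)), 0L)
  expect_error(subsample_reads(pool, 5, seed = 1), class = "mirsat_bad_subsample")
  expect_identical(subsample_reads(pool, 2, seed = 9), subsample_reads(pool, 2, seed = 9))
})

test_that("subsample counts follow the multivariate hypergeometric law", {
  # pool {A:3, B:1}, n = 2: enumeration of the 2-subsets gives
  # P(A = 2) = 3/6 and P(A = 1, B = 1) = 3/6
  pool <- collapse_reads(rep(c("AAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCC"), c(3, 1)))
  draws <- vapply(1:10000, function(i) {
    s <- subsample_reads(pool, 2, seed = i)
    sum(s$count[s$sequence == "AAAAAAAAAAAAAAAAAA"])
  }, numeric(1))
  obs <- c(sum(draws == 1), sum(draws == 2))
  expect_equal(sum(obs), 10000L) # A = 0 is impossible
  chi <- suppressWarnings(stats::chisq.test(obs, p = c(0.5, 0.5)))
  expect_gt(chi$p.value, 0.01)
})

test_that("detection curves match a from-scratch recount of their subsamples", {
  # toy: A has 60 reads, B has 4; threshold 5 detects only A at full depth
  ref2 <- mature_reference(tibble::tibble(
    mirna_id = c("A", "B"),
    sequence = c("ACGTACGTACGTACGTACGTAC", "TTGGCCAATTGGCCAATTGGCA")
  ))
  pool <- collapse_reads(rep(ref2$sequence, c(60, 4)))
  qf <- quantifier_exact(ref2)
  res <- detection_curve(pool, qf, start = 64, step = 10, thresholds = c(1, 5),
                         seed = 1, keep_subsamples = TRUE)
  full <- res$curve[res$curve$depth == 64, ]
  expect_equal(full$detected[full$threshold == 5], 1L)
  expect_equal(full$detected[full$threshold == 1], 2L)

  lib <- simulate_library(fix$ref, fix$profile, composition_profile(1, 0, 0, 0, 0),
                          sim_config(20000, seed = 5, isomir_other_rate = 0),
                          fix$decoys)
  pool2 <- preprocess_reads(lib$reads)$collapsed
  qf2 <- make_quantifier(fix$ref, fix$decoys)
  res2 <- detection_curve(pool2, qf2, start = 5000, step = 5000,
                          thresholds = c(1, 3, 5, 10, 50), seed = 2,
                          keep_subsamples = TRUE)
  # oracle: reclassify every emitted subsample from scratch and recount
  for (d in names(res2$subsamples)) {
    sub <- res2$subsamples[[d]]
    expect_equal(sum(sub$count), as.integer(d))
    oracle_counts <- quantify_sample(sub, fix$ref, fix$decoys)$counts
    for (t in c(1, 3, 5, 10, 50)) {
      got <- res2$curve$detected[res2$curve$depth == as.integer(d) &
                                   res2$curve$threshold == t]
      expect_equal(got, sum(oracle_counts >= t))
    }
  }
})

test_that("nested curves are monotone in depth and threshold, with consistent increments", {
  pool <- simulate_mapped_pool(fix$ref, fix$profile, 30000, seed = 8)
  qf <- quantifier_exact(fix$ref)
  for (sd in 1:5) {
    res <- detection_curve(pool, qf, start = 2000, step = 7000,
                           thresholds = c(1, 3, 5, 10, 50), seed = sd)
    cv <- res$curve
    for (t in unique(cv$threshold)) {
      d <- cv$detected[cv$threshold == t]
      expect_true(all(diff(d) >= 0))
      expect_equal(cv$new_detected[cv$threshold == t], c(d[1], diff(d)))
    }
    for (dep in unique(cv$depth)) {
      byt <- cv$detected[cv$depth == dep][order(unique(cv$threshold))]
      expect_true(all(diff(byt) <= 0))
    }
  }
  expect_error(detection_curve(pool, qf, start = 40000), class = "mirsat_bad_subsample")
})

test_that("spearman_rho matches a hand-coded average-rank computation", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1.0)
  expect_equal(spearman_rho(x, -x), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(10, 20, 20, 40)), 1.0)

  # oracle: Pearson on average ranks, written out
  manual_rho <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  a <- c(1, 2, 2, 3); b <- c(3, 1, 2, 2)
  expect_equal(spearman_rho(a, b), manual_rho(a, b))
  set.seed(11)
  for (i in 1:10) {
    a <- rpois(15, 4); b <- rpois(15, 4)
    if (length(unique(a)) > 1 && length(unique(b)) > 1) {
      expect_equal(spearman_rho(a, b), manual_rho(a, b))
      expect_equal(spearman_rho(a, b), spearman_rho(b, a))
    }
  }

  expect_error(spearman_rho(rep(1, 5), 1:5), class = "mirsat_constant_vector")
  expect_error(spearman_rho(1:3, 1:4), class = "mirsat_bad_input")
})

test_that("correlation curves end at exactly 1 and agree with manual ranks", {
  pool <- setNames(as.numeric(c(500, 300, 120, 60, 15, 5)), paste0("m", 1:6))
  res <- correlation_curve(pool, step = 200, seed = 4)
  expect_equal(res$curve$rho[nrow(res$curve)], 1.0)
  expect_true(all(res$curve$rho >= -1 & res$curve$rho <= 1))
  expect_error(correlation_curve(pool, step = 2000), class = "mirsat_bad_subsample")
  expect_error(correlation_curve(pool, step = 100, max_depth = 1e6),
               class = "mirsat_bad_subsample")

  # oracle on a tiny pool: recompute rho from the nested subsample by hand
  pool3 <- setNames(as.numeric(c(30, 12, 2)), c("a", "b", "c"))
  manual_rho <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  res3 <- correlation_curve(pool3, step = 11, seed = 6)
  perm <- mirsat:::nested_permutation(pool3, seed = 6)
  full <- tabulate(perm, nbins = 3)
  for (i in seq_len(nrow(res3$curve))) {
    sub <- tabulate(perm[seq_len(res3$curve$depth[i])], nbins = 3)
    if (length(unique(sub)) > 1) {
      expect_equal(res3$curve$rho[i], manual_rho(sub, full))
    }
  }
})

test_that("median correlation is non-decreasing with depth on simulated pools", {
  rhos <- sapply(1:20, function(sd) {
    pool <- simulate_mapped_pool(fix$ref, fix$profile, 40000, seed = 600 + sd)
    counts <- setNames(pool$count, attr(pool, "source_id"))
    correlation_curve(counts, step = 8000, seed = sd)$curve$rho
  })
  med <- apply(rhos, 1, median)
  expect_true(all(diff(med) >= -1e-12))
  expect_equal(med[length(med)], 1.0)
})

test_that("detection overlap partitions 2 and 3 sets completely", {
  two <- detection_overlap(list(P = c("A", "B", "C"), Q = c("B", "C", "D")))
  expect_equal(two$count[two$region == "P"], 1L)
  expect_equal(two$count[two$region == "Q"], 1L)
  expect_equal(two$count[two$region == "P&Q"], 2L)
  expect_equal(sum(two$count), 4L)

  s <- c("x", "y")
  three <- detection_overlap(list(a = s, b = s, c = s))
  expect_equal(three$count[three$region == "a&b&c"], 2L)
  expect_equal(sum(three$count), 2L)

  disj <- detection_overlap(list(a = "1", b = "2", c = "3"))
  expect_equal(disj$count[disj$region %in% c("a", "b", "c")], rep(1L, 3))
  expect_equal(sum(disj$count), 3L)

  expect_error(detection_overlap(list(a = s)), class = "mirsat_bad_input")
  expect_error(detection_overlap(list(a = s, b = s, c = s, d = s)),
               class = "mirsat_bad_input")
})
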