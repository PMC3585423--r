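test_that("align_read spans the mature / others / unclassified decision surface", {
  ref <- fix$ref
  s <- ref$sequence[5]

  exact <- align_read(s, ref, fix$decoys)
  expect_equal(exact$category, "mature")
  expect_equal(exact$mirna_id, ref$mirna_id[5])
  expect_equal(exact$n_mismatches, 0L)
  expect_equal(exact$three_prime_offset, 0L)

  # one internal substitution stays mature with n_mismatches = 1
  s1 <- s
  old <- substr(s1, 10, 10)
  substr(s1, 10, 10) <- setdiff(c("A", "C", "G", "T"), old)[1]
  snv <- align_read(s1, ref, fix$decoys)
  expect_equal(snv$category, "mature")
  expect_equal(snv$mirna_id, ref$mirna_id[5])
  expect_equal(snv$n_mismatches, 1L)

  # 4-nt 3' extension exceeds the +/-2 window: others_isomir
  ext <- align_read(paste0(s, "AAAA"), ref, fix$decoys)
  expect_equal(ext$category, "others_isomir")
  expect_equal(ext$mirna_id, ref$mirna_id[5])
  expect_equal(ext$three_prime_offset, 4L)

  # in-window 2-nt trim stays mature
  tr <- align_read(substr(s, 1, nchar(s) - 2), ref, fix$decoys)
  expect_equal(tr$category, "mature")
  expect_equal(tr$three_prime_offset, -2L)

  expect_error(align_read(strrep("A", 10), ref), class = "mirsat_short_sequence")
  expect_error(
    align_read(s, tibble::tibble(mirna_id = character(0), sequence = character(0))),
    class = "mirsat_empty_reference"
  )
})

test_that("sequences far from every mature entry are unclassified (brute-force check)", {
  ref <- fix$ref
  set.seed(77)
  found <- 0L
  while (found < 5L) {
    cand <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
    d16 <- vapply(ref$sequence, function(r) {
      oracle_hamming(substr(cand, 1, 16), substr(r, 1, 16))
    }, numeric(1))
    dov <- vapply(ref$sequence, function(r) oracle_hamming(cand, r), numeric(1))
    if (all(d16 >= 2) && all(dov >= 2)) {
      expect_equal(align_read(cand, ref)$category, "unclassified")
      found <- found + 1L
    }
  }
})

test_that("decoy reads classify to their pool and decoys stay clear of matures", {
  nc <- fix$decoys$ncrna$sequence[3]
  out <- align_read(nc, fix$ref, fix$decoys)
  expect_equal(out$category, "ncrna")
  rp <- align_read(fix$decoys$`repeat`$sequence[1], fix$ref, fix$decoys)
  expect_equal(rp$category, "repeat")
  # construction guarantee: >= 3 mismatches over the first 16 nt
  for (pool in fix$decoys) {
    d <- vapply(pool$sequence[1:5], function(s) {
      min(vapply(fix$ref$sequence, function(r) {
        oracle_hamming(substr(s, 1, 16), substr(r, 1, 16))
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(d >= 3))
  }
})

test_that("multimapper policies allocate mass as specified", {
  asg <- tibble::tibble(candidates = list(c("X", "Y")), count = 1)
  ids <- c("X", "Y", "Z")
  expect_equal(resolve_multimappers(asg, ids, "uniform"),
               c(X = 0.5, Y = 0.5, Z = 0))
  expect_equal(resolve_multimappers(asg, ids, "discard"),
               c(X = 0, Y = 0, Z = 0))
  expect_error(
    resolve_multimappers(tibble::tibble(candidates = list(character(0)), count = 1), ids),
    class = "mirsat_bad_assignment"
  )
})

test_that("EM redistribution matches an independently coded fixed-point iteration", {
  # unique evidence X:90, Y:10 plus 100 shared reads
  asg <- tibble::tibble(
    candidates = c(replicate(1, list("X")), replicate(1, list("Y")),
                   replicate(1, list(c("X", "Y")))),
    count = c(90, 10, 100)
  )
  got <- resolve_multimappers(asg, c("X", "Y"), "em")

  # oracle: plain fixed-point iteration coded from scratch
  px <- 90; py <- 10
  for (i in 1:1000) {
    ax <- 90 + 100 * px / (px + py)
    ay <- 10 + 100 * py / (px + py)
    if (max(abs(c(ax - px, ay - py))) < 1e-12) break
    px <- ax; py <- ay
  }
  expect_equal(got, c(X = px, Y = py), tolerance = 1e-6)
  expect_equal(sum(got), 200)
  # shared mass splits ~ 90/10
  expect_equal(got[["X"]] - 90, 90, tolerance = 0.01)

  # a component with no unique evidence falls back to uniform, with a message
  asg2 <- tibble::tibble(candidates = list(c("A", "B")), count = 10)
  expect_message(
    out <- resolve_multimappers(asg2, c("A", "B"), "em"),
    "uniform"
  )
  expect_equal(out, c(A = 5, B = 5))
})

test_that("RPM follows the printed formula exactly", {
  expect_equal(compute_rpm(50, 2e6), 25)
  expect_equal(compute_rpm(1234, 1234), 1e6)
  expect_equal(compute_rpm(0, 1000), 0)
  expect_error(compute_rpm(5, 0), class = "mirsat_bad_library_size")
  expect_error(compute_rpm(-1, 10), class = "mirsat_bad_counts")
})

test_that("detection sets follow thresholds and are monotone", {
  counts <- c(A = 5, B = 1)
  expect_setequal(detection_set(counts, 1), c("A", "B"))
  expect_setequal(detection_set(counts, 5), "A")
  expect_length(detection_set(c(A = 0, B = 0), 50), 0L)
  expect_error(detection_set(counts, 0))

  set.seed(4)
  for (i in 1:20) {
    x <- setNames(rpois(30, 3), paste0("g", 1:30))
    t1 <- sample(1:5, 1); t2 <- t1 + sample(1:5, 1)
    expect_true(all(detection_set(x, t2) %in% detection_set(x, t1)))
  }
})

test_that("quantification conserves mass and recovers ledger truth without errors", {
  comp <- composition_muscle()
  cfg <- sim_config(30000, seed = 17, isomir_rate = 0, snv_rate = 0)
  lib <- simulate_library(fix$ref, fix$profile, comp, cfg, fix$decoys)
  pre <- preprocess_reads(lib$reads)
  q <- quantify_sample(pre$collapsed, fix$ref, fix$decoys)

  led <- lib$ledger
  n_mirna_reads <- sum(led$category == "mirna")
  expect_equal(sum(q$counts), n_mirna_reads)
  expect_equal(q$library_size, n_mirna_reads)

  # with no isomiR edits and no substitutions every miRNA read maps to its
  # ledger source (exactness under the >= 3-Hamming separation)
  truth_counts <- table(led$source_id[led$category == "mirna"])
  got <- q$counts[names(truth_counts)]
  expect_equal(unname(got), as.numeric(truth_counts))

  # em conserves the same mass
  qem <- quantify_sample(pre$collapsed, fix$ref, fix$decoys, policy = "em")
  expect_equal(sum(qem$counts), n_mirna_reads)
})

test_that("composition breakdown sums to 1 and tracks the ledger", {
  allm <- collapse_reads(fix$ref$sequence[rep(1:5, 10)])
  q <- quantify_sample(allm, fix$ref, fix$decoys)
  expect_equal(unname(q$composition$fractions["mature"]), 1.0)
  expect_equal(sum(q$composition$fractions), 1, tolerance = 1e-12)

  lib <- simulate_library(fix$ref, fix$profile, composition_muscle(),
                          sim_config(50000, seed = 23), fix$decoys)
  pre <- preprocess_reads(lib$reads)
  q <- quantify_sample(pre$collapsed, fix$ref, fix$decoys)
  led <- lib$ledger[lib$ledger$read_id %in% pre$reads$read_id, ]
  ledger_frac <- c(
    mature = mean(led$category == "mirna"),
    ncrna = mean(led$category == "ncrna"),
    "repeat" = mean(led$category == "repeat"),
    unclassified = mean(led$category %in% c("unclassified", "isomir_other"))
  )
  expect_equal(q$composition$fractions, ledger_frac, tolerance = 0.01)
  # the isomiR "others" fraction sits inside the observed 1-12% band
  expect_gt(q$composition$others_isomir, 0.01)
  expect_lt(q$composition$others_isomir, 0.12)
})

test_that("RPM rescales linearly under subsampling in expectation", {
  pool <- simulate_mapped_pool(fix$ref, fix$profile, 20000, seed = 3)
  qf <- quantifier_exact(fix$ref)
  full_counts <- qf(pool)
  full_rpm <- compute_rpm(full_counts, sum(full_counts))
  sub_rpm <- matrix(0, nrow = length(full_rpm), ncol = 50)
  for (i in 1:50) {
    sub <- subsample_reads(pool, 5000, seed = 1000 + i)
    sub_rpm[, i] <- compute_rpm(qf(sub), 5000)
  }
  hi <- full_counts >= 100
  expect_equal(rowMeans(sub_rpm)[hi], unname(full_rpm[hi]), tolerance = 0.05)
})

test_that("count tables align samples and round at the integer boundary", {
  libs <- lapply(1:3, function(k) {
    lib <- simulate_library(fix$ref, fix$profile, composition_muscle(),
                            sim_config(5000, seed = 100 + k), fix$decoys)
    quantify_sample(preprocess_reads(lib$reads)$collapsed, fix$ref, fix$decoys)
  })
  ct <- count_table(setNames(libs, paste0("s", 1:3)))
  expect_equal(dim(ct$counts), c(40L, 3L))
  expect_equal(unname(colSums(ct$counts)), unname(ct$library_sizes))
  expect_message(round_counts(ct$counts * 1.0001), "rounded")
  expect_silent(ri <- round_counts(round(ct$counts)))
  expect_true(all(ri == floor(ri)))
})
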