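#' Subsample reads without replacement from a collapsed pool
#'
#' Sampling is at the individual-read level (multivariate hypergeometric on
#' the per-sequence multiplicities), which preserves the original read
#' distribution - the reason the resampling procedures select reads rather
#' than miRNAs.
#'
#' @param pool Collapsed read set (`sequence`, `count`).
#' @param n Number of reads to draw (`0 <= n <= sum(pool$count)`).
#' @param seed Integer seed.
#' @return Collapsed read set of the subsample (sequences with sampled
#'   count > 0, canonical order).
#' @export
subsample_reads <- function(pool, n, seed = 1L) {
  total <- sum(pool$count)
  if (n < 0 || n > total) {
    stop_mirsat(sprintf("cannot draw %s reads from a pool of %s", n, total),
                "mirsat_bad_subsample")
  }
  idx <- rep.int(seq_len(nrow(pool)), pool$count)
  take <- with_seed(seed, sample(idx, n))
  cnt <- tabulate(take, nbins = nrow(pool))
  keep <- cnt > 0L
  out <- tibble::tibble(sequence = pool$sequence[keep], count = cnt[keep])
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
  attr(out, "total") <- n
  class(out) <- c("mirsat_collapsed", class(out))
  out
}

# one random permutation of the pool's expanded read indices; the first d
# elements are the nested depth-d subsample
nested_permutation <- function(pool_counts, seed) {
  idx <- rep.int(seq_along(pool_counts), pool_counts)
  with_seed(seed, sample(idx))
}

#' Build a quantifier closure for saturation analysis
#'
#' `make_quantifier()` runs the full single-SNV quantifier on each
#' subsample. `quantifier_exact()` is for pools of exact mature sequences
#' (e.g. [simulate_mapped_pool()]): it maps each sequence to its reference
#' id by lookup.
#'
#' @inheritParams quantify_sample
#' @return A function `collapsed -> named per-miRNA counts`.
#' @export
make_quantifier <- function(ref, decoys = NULL, max_snv = 1L,
                            three_prime_window = 2L, policy = "uniform") {
  force(ref); force(decoys)
  function(collapsed) {
    quantify_sample(collapsed, ref, decoys, max_snv, three_prime_window, policy)$counts
  }
}

#' @rdname make_quantifier
#' @export
quantifier_exact <- function(ref) {
  force(ref)
  function(collapsed) {
    hit <- match(collapsed$sequence, ref$sequence)
    if (anyNA(hit)) {
      stop_mirsat("quantifier_exact: pool contains non-reference sequences",
                  "mirsat_bad_pool")
    }
    counts <- setNames(numeric(nrow(ref)), ref$mirna_id)
    s <- rowsum(collapsed$count, ref$mirna_id[hit])
    counts[rownames(s)] <- as.numeric(s)
    counts
  }
}

#' Detection-saturation curve over sequencing depth
#'
#' Starting from `start` reads and adding `step` reads at a time, quantifies
#' each cumulative (nested) subsample of the post-clipped pool and counts
#' the miRNAs detected at each read-count threshold, plus the newly detected
#' miRNAs per increment. Nesting makes new-detection counts well-defined and
#' non-negative; set `nested = FALSE` for independent draws per depth.
#'
#' @param pool Collapsed read set of post-clipped (or mapped) reads.
#' @param quantifier Function `collapsed -> named per-miRNA counts`
#'   (see [make_quantifier()]).
#' @param start First depth (default 500,000 reads).
#' @param step Depth increment (default 1,000,000 reads).
#' @param thresholds Detection thresholds (default 1, 3, 5, 10, 50).
#' @param seed Integer seed.
#' @param nested Nested (cumulative) subsamples (default) or independent
#'   draws per depth.
#' @param keep_subsamples Also return each depth's collapsed subsample.
#' @return List of class `mirsat_saturation`: `curve` (tibble `depth`,
#'   `threshold`, `detected`, `new_detected`), `seed`, and optionally
#'   `subsamples`.
#' @export
detection_curve <- function(pool, quantifier, start = 500000L, step = 1000000L,
                            thresholds = c(1, 3, 5, 10, 50), seed = 1L,
                            nested = TRUE, keep_subsamples = FALSE) {
  total <- sum(pool$count)
  if (total < start) {
    stop_mirsat("pool total is smaller than the starting depth", "mirsat_bad_subsample")
  }
  depths <- seq(start, total, by = step)
  perm <- if (nested) nested_permutation(pool$count, seed) else NULL
  subsamples <- if (keep_subsamples) vector("list", length(depths)) else NULL
  det <- matrix(0L, nrow = length(depths), ncol = length(thresholds))
  for (i in seq_along(depths)) {
    d <- depths[i]
    if (nested) {
      cnt <- tabulate(perm[seq_len(d)], nbins = nrow(pool))
      keep <- cnt > 0L
      sub <- tibble::tibble(sequence = pool$sequence[keep], count = cnt[keep])
      attr(sub, "total") <- d
      class(sub) <- c("mirsat_collapsed", class(sub))
    } else {
      sub <- subsample_reads(pool, d, derive_seed(seed, i))
    }
    counts <- tryCatch(
      quantifier(sub),
      error = function(e) {
        stop_mirsat(sprintf("quantifier failed at depth %d: %s", d, conditionMessage(e)),
                    "mirsat_quantifier_failure")
      }
    )
    det[i, ] <- vapply(thresholds, function(t) length(detection_set(counts, t)), integer(1))
    if (keep_subsamples) subsamples[[i]] <- sub
  }
  # expand_grid varies threshold fastest within depth, matching t(det)
  curve <- tidyr::expand_grid(depth = depths, threshold = thresholds)
  curve$detected <- as.integer(t(det))
  curve <- dplyr::arrange(curve, .data$threshold, .data$depth)
  curve <- dplyr::mutate(
    dplyr::group_by(curve, .data$threshold),
    new_detected = .data$detected - dplyr::lag(.data$detected, default = 0L)
  )
  curve <- dplyr::ungroup(curve)
  out <- list(curve = curve, seed = seed, nested = nested)
  if (keep_subsamples) out$subsamples <- setNames(subsamples, depths)
  structure(out, class = "mirsat_saturation")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Constant vectors make the
#' coefficient undefined and raise an explicit error rather than returning
#' NaN.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_mirsat("spearman_rho needs two vectors of equal length >= 2", "mirsat_bad_input")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_mirsat("spearman_rho is undefined for a constant vector", "mirsat_constant_vector")
  }
  cor(x, y, method = "spearman")
}

#' Correlation-adequacy curve: subsampled profile vs full-depth profile
#'
#' From the mapped-read pool, draws nested subsamples at depths `step`,
#' `2*step`, ... up to `max_depth`, builds each depth's per-miRNA count
#' profile, and reports its Spearman correlation against the full
#' (`max_depth`) profile over the miRNAs detected at full depth (zeros
#' imputed for the subsample). The final depth correlates the full profile
#' with itself, so rho there is exactly 1.
#'
#' @param pool Named per-miRNA mapped-read counts.
#' @param step Depth increment (default 100,000 reads).
#' @param max_depth Largest depth (default: the pool total).
#' @param seed Integer seed.
#' @return List of class `mirsat_correlation`: `curve` (tibble `depth`,
#'   `rho`), `seed`.
#' @export
correlation_curve <- function(pool, step = 100000L, max_depth = NULL, seed = 1L) {
  total <- sum(pool)
  max_depth <- max_depth %||% total
  if (max_depth > total) {
    stop_mirsat("max_depth exceeds the pool total", "mirsat_bad_subsample")
  }
  if (step > max_depth) {
    stop_mirsat("step exceeds max_depth", "mirsat_bad_subsample")
  }
  depths <- seq(step, max_depth, by = step)
  if (depths[length(depths)] != max_depth) depths <- c(depths, max_depth)
  perm <- nested_permutation(pool, seed)
  full <- tabulate(perm[seq_len(max_depth)], nbins = length(pool))
  support <- which(full > 0L)
  rho <- vapply(depths, function(d) {
    sub <- tabulate(perm[seq_len(d)], nbins = length(pool))
    if (identical(sub[support], full[support])) return(1) # exact at full depth
    spearman_rho(sub[support], full[support])
  }, numeric(1))
  structure(
    list(curve = tibble::tibble(depth = depths, rho = rho), seed = seed),
    class = "mirsat_correlation"
  )
}

#' Overlap partition of 2 or 3 detection sets
#'
#' @param sets Named list of 2 or 3 character vectors (detection sets).
#' @return Tibble `region`, `count`: one row per non-empty-membership region
#'   of the Venn partition; counts sum to the size of the union.
#' @export
detection_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop_mirsat("detection_overlap supports exactly 2 or 3 named sets", "mirsat_bad_input")
  }
  nm <- names(sets) %||% LETTERS[seq_along(sets)]
  if (is.null(names(sets)) || any(!nzchar(nm))) nm <- LETTERS[seq_along(sets)]
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) member <- matrix(member, nrow = 1L)
  pat <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(nm), function(k) {
    apply(utils::combn(nm, k), 2L, paste, collapse = "&")
  }))
  cnt <- table(factor(pat, levels = combos))
  tibble::tibble(region = combos, count = as.integer(cnt))
}
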