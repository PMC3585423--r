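#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values: per-sample scaling factors computed
#' from log expression ratios against a reference sample, after doubly
#' trimming the M-values (log-ratios, default 30% each side) and A-values
#' (average log abundance, default 5% each side). Genes with a zero count in
#' either the sample or the reference are excluded; weights are
#' inverse-variance (delta-method) weights; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Non-negative matrix, genes x samples (>= 2 samples).
#' @param ref_sample Reference column index; by default the sample whose
#'   upper quartile of library-size-scaled counts is closest to the mean
#'   upper quartile.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Named numeric factors, geometric mean 1, class
#'   `mirsat_norm_factors` with attribute `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L, all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop_mirsat("a library has zero total count", "mirsat_bad_counts")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2L, function(x) quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  r <- counts[, ref_sample]
  Nr <- lib[ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_sample) return(1)
    x <- counts[, j]
    Nj <- lib[j]
    keep <- x > 0 & r > 0
    xk <- x[keep]; rk <- r[keep]
    M <- log2((xk / Nj) / (rk / Nr))
    A <- 0.5 * log2((xk / Nj) * (rk / Nr))
    w <- (Nj - xk) / (Nj * xk) + (Nr - rk) / (Nr * rk)
    loM <- quantile(M, trim_m); hiM <- quantile(M, 1 - trim_m)
    loA <- quantile(A, trim_a); hiA <- quantile(A, 1 - trim_a)
    use <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (sum(use) < 2L) {
      stop_mirsat(sprintf(
        "TMM: fewer than 2 genes survive trimming for sample %d (of %d shared nonzero genes)",
        j, sum(keep)
      ), "mirsat_tmm_degenerate")
    }
    2^(sum(M[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(setNames(f, colnames(counts) %||% as.character(seq_along(f))),
            class = "mirsat_norm_factors", ref_sample = ref_sample)
}

#' Median-of-ratios size factors
#'
#' `sf_j = median_i(count_ij / geometric-mean_i)` over genes with a nonzero
#' count in every sample.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @return Named positive size factors, class `mirsat_norm_factors`.
#' @export
median_ratio_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  nz <- rowSums(counts == 0) == 0L
  if (!any(nz)) {
    stop_mirsat("no gene has a nonzero count in every sample", "mirsat_no_common_genes")
  }
  x <- counts[nz, , drop = FALSE]
  gm <- exp(rowMeans(log(x)))
  sf <- apply(x / gm, 2L, median)
  structure(setNames(sf, colnames(counts) %||% as.character(seq_along(sf))),
            class = "mirsat_norm_factors")
}

#' Method-of-moments common dispersion
#'
#' Counts are first scaled to a common effective library size; within each
#' group with >= 2 replicates, each gene contributes the moment estimate
#' `phi_g = (s^2 - mu) / (mu^2 - s^2/n)` implied by the NB variance function
#' `var = mu + phi * mu^2` (the `- s^2/n` term removes the upward bias of
#' the squared sample mean as an estimate of `mu^2`; without it the
#' estimator is biased low and the downstream exact test anti-conservative).
#' The common dispersion is the inverse-variance-weighted mean of the
#' per-gene estimates, with weights `(mu / (1 + phi0 * mu))^2` from a
#' first-pass pooled fit: a plain ratio-of-sums pool is dominated by the few
#' most abundant genes (weights proportional to `mu^2`) and therefore very
#' noisy on the long-tailed profiles this package simulates, while the
#' saturating weights give every well-measured gene comparable influence.
#' `phi = 0` degenerates the model to Poisson.
#'
#' @param counts Count matrix, genes x samples.
#' @param groups Two-level factor over the columns.
#' @param effective_sizes Per-sample effective library sizes (default the
#'   column sums; multiply by normalization factors for TMM).
#' @return Single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       effective_sizes = colSums(counts)) {
  groups <- as.factor(groups)
  if (!any(table(groups) >= 2L)) {
    stop_mirsat("dispersion is unidentifiable without replicates in some group",
                "mirsat_no_replicates")
  }
  N0 <- sort(effective_sizes)[ceiling(length(effective_sizes) / 2)]
  z <- sweep(counts, 2L, N0 / effective_sizes, `*`)
  num <- 0
  den <- 0
  for (g in levels(groups)) {
    zg <- z[, groups == g, drop = FALSE]
    n <- ncol(zg)
    if (n < 2L) next
    mu <- rowMeans(zg)
    s2 <- apply(zg, 1L, var)
    ok <- mu > 1 & (mu^2 - s2 / n) > 0
    if (!any(ok)) next
    phi_g <- (s2[ok] - mu[ok]) / (mu[ok]^2 - s2[ok] / n)
    phi0 <- max(0, sum(s2[ok] - mu[ok]) / sum(mu[ok]^2 - s2[ok] / n))
    w <- (mu[ok] / (1 + phi0 * mu[ok]))^2
    num <- num + sum(w * phi_g)
    den <- den + sum(w)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# two-sided conditional exact p-value for one gene: group sums s1, s2 with
# n1, n2 libraries at common dispersion phi. Conditions on t = s1 + s2;
# the conditional law of s1 is free of the mean (binomial for phi = 0,
# Dirichlet-multinomial-type for phi > 0). Two-sided by summing the
# probabilities of outcomes no more likely than the observed one.
exact_test_p <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  s <- 0:t
  if (phi <= 0) {
    lp <- dbinom(s, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    lp <- dnbinom(s, size = r1, prob = 0.5, log = TRUE) +
      dnbinom(t - s, size = r2, prob = 0.5, log = TRUE)
    lp <- lp - max(lp)
  }
  p <- exp(lp)
  p <- p / sum(p)
  min(1, sum(p[p <= p[s1 + 1] * (1 + 1e-10)]))
}

#' Negative-binomial conditional exact test between two groups
#'
#' For each gene, counts are equalized to a common library size (each
#' sample scaled to the median of the effective sizes and rounded
#' half-to-even to pseudo-counts), the test conditions on the gene's total
#' pseudo-count, and the two-sided exact probability that group 1's sum is
#' as or more extreme is computed under a negative binomial with common
#' dispersion `phi`. With `phi = 0` the conditional law is exactly
#' binomial. The lower median (an order statistic, rather than, say, the
#' geometric mean) is used as the common scale because it is untouched when
#' a single non-central library's counts are rescaled: that rescaling then
#' changes its own pseudo-counts not at all and no other library's pseudo-
#' counts either, so every p-value survives exactly. Log2 fold changes (group 2
#' vs group 1) come from normalized group means with a 0.5 pseudo-count
#' guarding zero means; the pseudo-count is never used for testing.
#'
#' @param counts Integer count matrix, genes x samples (fractional counts
#'   must be rounded with [round_counts()] first).
#' @param groups Two-level factor over the columns.
#' @param phi Common dispersion (>= 0).
#' @param effective_sizes Per-sample effective library sizes (library size
#'   times normalization factor).
#' @return Tibble: `mirna_id`, `log2fc`, `pvalue`.
#' @export
nb_exact_test <- function(counts, groups, phi,
                          effective_sizes = colSums(counts)) {
  if (any(counts != floor(counts))) {
    stop_mirsat("nb_exact_test requires integer counts; round with round_counts() at the quantification boundary",
                "mirsat_noninteger_counts")
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop_mirsat("nb_exact_test compares exactly two groups", "mirsat_bad_groups")
  }
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  # lower median: an order statistic, stable under rescaling of any single
  # library that sits above it
  N0 <- sort(effective_sizes)[ceiling(length(effective_sizes) / 2)]
  pseudo <- round(sweep(counts, 2L, N0 / effective_sizes, `*`))
  s1 <- rowSums(pseudo[, g1, drop = FALSE])
  s2 <- rowSums(pseudo[, !g1, drop = FALSE])
  p <- vapply(seq_along(s1), function(i) exact_test_p(s1[i], s2[i], n1, n2, phi),
              numeric(1))
  norm <- sweep(counts, 2L, N0 / effective_sizes, `*`)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])
  tibble::tibble(
    mirna_id = rownames(counts) %||% as.character(seq_along(s1)),
    log2fc = unname(log2((m2 + 0.5) / (m1 + 0.5))),
    pvalue = p
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order, each >= its raw p.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop_mirsat("p-values must lie in [0, 1]", "mirsat_bad_pvalues")
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression with FDR control
#'
#' The full pipeline stage: normalization (TMM or median-of-ratios),
#' common-dispersion estimation, per-gene NB conditional exact test, BH
#' adjustment and significance flags at `alpha`.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param groups Two-level factor.
#' @param normalization `"tmm"` (default) or `"median_ratio"`.
#' @param phi Common dispersion; estimated from the data when `NULL`.
#' @param alpha FDR level (default 0.05).
#' @return List of class `mirsat_de`: `table` (tibble `mirna_id`, `log2fc`,
#'   `pvalue`, `padj`, `significant`, sorted by `padj`), `phi`,
#'   `normalization`, `effective_sizes`.
#' @export
de_exact_test <- function(counts, groups,
                          normalization = c("tmm", "median_ratio"), phi = NULL,
                          alpha = 0.05) {
  normalization <- match.arg(normalization)
  eff <- switch(normalization,
    tmm = colSums(counts) * as.numeric(tmm_factors(counts)),
    median_ratio = {
      sf <- as.numeric(median_ratio_size_factors(counts))
      sf / exp(mean(log(sf))) * exp(mean(log(colSums(counts))))
    }
  )
  phi <- phi %||% estimate_common_dispersion(counts, groups, eff)
  tab <- nb_exact_test(counts, groups, phi, eff)
  tab$padj <- bh_adjust(tab$pvalue)
  tab$significant <- tab$padj <= alpha
  tab <- dplyr::arrange(tab, .data$padj, .data$pvalue)
  structure(
    list(table = tab, phi = phi, normalization = normalization,
         effective_sizes = eff, alpha = alpha),
    class = "mirsat_de"
  )
}

#' Two-sample t test (validation-table utility)
#'
#' Welch (default) or pooled two-sample t test. When both groups have zero
#' variance and equal means, the statistic is defined as 0 with p = 1 (and
#' a message); with unequal means, p = 0.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
group_t_test <- function(group_a, group_b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      message("group_t_test: both groups constant and equal; p = 1 by convention")
      return(list(statistic = 0, df = length(group_a) + length(group_b) - 2L, p_value = 1))
    }
    return(list(
      statistic = sign(mean(group_a) - mean(group_b)) * Inf,
      df = length(group_a) + length(group_b) - 2L, p_value = 0
    ))
  }
  tt <- t.test(group_a, group_b, var.equal = (variant == "pooled"))
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
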