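# Independently coded brute-force oracles for the normalization operations.
# Deliberately written as plain loops, separate from the package's
# vectorized implementations.

oracle_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      x <- counts[g, j]; r <- counts[g, ref]
      if (x > 0 && r > 0) {
        pj <- x / lib[j]; pr <- r / lib[ref]
        M <- c(M, log2(pj / pr))
        A <- c(A, 0.5 * log2(pj * pr))
        w <- c(w, (lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    keep <- M >= quantile(M, trim_m) & M <= quantile(M, 1 - trim_m) &
      A >= quantile(A, trim_a) & A <= quantile(A, 1 - trim_a)
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

oracle_median_ratio <- function(counts) {
  keep <- apply(counts, 1, function(x) all(x > 0))
  x <- counts[keep, , drop = FALSE]
  gm <- apply(x, 1, function(v) prod(v)^(1 / length(v)))
  apply(sweep(x, 1, gm, `/`), 2, median)
}

random_table <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    mu <- exp(rnorm(n_genes, 4, 1.5))
    matrix(rpois(n_genes * n_samples, rep(mu, n_samples)), nrow = n_genes,
           dimnames = list(paste0("g", seq_len(n_genes)),
                           paste0("s", seq_len(n_samples))))
  })
}
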