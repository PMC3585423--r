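#' @importFrom rlang %||% abort warn
#' @importFrom stats cor median quantile rgamma rnbinom rnorm rpois runif
#'   setNames var dbinom dnbinom p.adjust t.test
#' @importFrom utils head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-stream seed from a global seed
#'
#' One global integer seed fans out to independent per-library (or per-stage)
#' seeds by a fixed integer hash, so that simulating library `k` of an
#' experiment gives the same reads whether it is generated alone or as part
#' of the full design. All arithmetic stays below 2^53 and the result below
#' 2^31, so the value is exactly representable and a valid `set.seed()` input.
#'
#' @param seed Integer global seed.
#' @param stream Non-negative integer stream index.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  for (x in c(stream + 1, 99991)) {
    s <- (s * 48271 + x * 12345) %% m
  }
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Hamming distance over the 5'-anchored overlap of paired strings
#'
#' For each pair `x[i]`, `y[i]`, counts mismatching characters over the first
#' `min(nchar(x[i]), nchar(y[i]), cap)` positions. This 5'-anchored bounded
#' comparison is the primitive behind single-SNV read-to-reference matching.
#'
#' @param x,y Character vectors of equal length.
#' @param cap Optional maximum number of leading positions to compare.
#' @return Integer vector of mismatch counts.
#' @export
hamming_overlap <- function(x, y, cap = Inf) {
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(i) {
    a <- charToRaw(x[[i]])
    b <- charToRaw(y[[i]])
    n <- min(length(a), length(b), cap)
    if (n == 0L) return(0L)
    sum(a[seq_len(n)] != b[seq_len(n)])
  }, integer(1))
}

# Random DNA strings with per-element lengths. Vectorized: draws a character
# matrix at the maximum length and truncates per element.
rand_dna <- function(n, lengths) {
  if (n == 0L) return(character(0))
  lengths <- rep_len(lengths, n)
  maxlen <- max(lengths)
  m <- matrix(sample(DNA_BASES, n * maxlen, replace = TRUE), nrow = n)
  full <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  substr(full, 1L, lengths)
}

# TRUE for strings containing `pattern` as a fixed substring.
contains_fixed <- function(x, pattern) {
  grepl(pattern, x, fixed = TRUE)
}

stop_mirsat <- function(msg, class) {
  abort(msg, class = c(class, "mirsat_error"))
}
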