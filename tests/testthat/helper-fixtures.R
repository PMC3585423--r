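# Shared small fixtures, built once per test run.

fix <- local({
  ref <- build_reference(40, seed = 101)
  decoys <- decoy_pools(ref, seed = 102,
                        n_each = c(ncrna = 40L, "repeat" = 25L, unclassified = 60L))
  profile <- simulate_abundances(ref, seed = 103)
  list(ref = ref, decoys = decoys, profile = profile,
       adapter = "TGGAATTCTCGGGTGCCAAGG")
})

# assemble a synthetic read (insert + adapter + random padding to `cycles`)
make_read <- function(insert, adapter = fix$adapter, cycles = 50L, pad = "A") {
  full <- paste0(insert, adapter)
  if (nchar(full) < cycles) {
    full <- paste0(full, strrep(pad, cycles - nchar(full)))
  }
  substr(full, 1, cycles)
}

make_read_set <- function(sequences, phred = 35L) {
  q <- vapply(nchar(sequences),
              function(n) strrep(rawToChar(as.raw(33L + phred)), n), character(1))
  read_set(sprintf("t%04d", seq_along(sequences)), sequences, q)
}

# independent slow Hamming for oracle checks
oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- min(length(x), length(y))
  sum(x[seq_len(n)] != y[seq_len(n)])
}
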