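# Shared study parameters for the analysis scripts. Every script sources
# this file and derives its own RNG streams from GLOBAL_SEED, so any script
# can be rerun in isolation and reproduce its numbers exactly.

library(mirsat)

GLOBAL_SEED <- 20260922L

N_MIRNAS <- 300L      # reference size
N_READS <- 200000L    # reads per demonstration library
DEPTH_POOL <- 6500000 # mapped-read pool for the saturation curve
DEPTH_CORR <- 1000000 # mapped-read pool for the correlation curve
DE_DEPTH <- 30000     # mapped reads per library in the DE study
DE_PHI <- 0.1         # common dispersion of replicate counts
N_PER_GROUP <- 9L     # replicates per group

make_study <- function(seed = GLOBAL_SEED, n_mirnas = N_MIRNAS) {
  ref <- build_reference(n_mirnas, seed = derive_seed(seed, 1))
  list(
    ref = ref,
    decoys = decoy_pools(ref, seed = derive_seed(seed, 2)),
    profile = simulate_abundances(ref, seed = derive_seed(seed, 3))
  )
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
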