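#' Simulation configuration for one synthetic library
#'
#' Bundles the per-library generator settings. The defaults emulate a
#' 50-cycle Illumina small RNA run with TruSeq 3' adapter read-through:
#' every insert is followed by the adapter and random padding out to
#' `read_length` cycles, so adapter clipping is always exercised.
#'
#' @param n_reads Number of reads to emit (>= 0).
#' @param seed Integer seed; a fixed config is byte-identical on rerun.
#' @param adapter 3' adapter sequence (default the Illumina TruSeq small RNA
#'   adapter `TGGAATTCTCGGGTGCCAAGG`).
#' @param read_length Sequencing cycles (default 50).
#' @param isomir_rate Probability that a miRNA-category read carries an
#'   in-tolerance 3' modification (trim of 1-2 nt or templated-free extension
#'   of 1-2 nt). Default 0.2, reflecting the pervasive 3' heterogeneity of
#'   mature miRNAs.
#' @param isomir_other_rate Fraction of post-clipped reads that are
#'   out-of-tolerance 3' isomiRs (extension of 3-5 nt, or a 3-nt trim when the
#'   source allows it). These reads are carved out of the unclassified budget
#'   and land in the quantifier's "others" ledger; the default 5% sits inside
#'   the 1-12% band observed for muscle libraries.
#' @param snv_rate Probability that a miRNA-category read carries one
#'   substitution sequencing error (default 0.1, i.e. roughly a 0.5% per-base
#'   error rate over a 22-nt insert).
#' @param base_phred Constant per-base quality (default Q35).
#' @param degrade_position Optional cycle index whose quality is degraded to
#'   `degrade_phred` in every read (for QC testing).
#' @param degrade_phred Quality used at `degrade_position`.
#' @return List of class `mirsat_sim_config`.
#' @export
sim_config <- function(n_reads, seed = 1L, adapter = ILLUMINA_3P_ADAPTER,
                       read_length = 50L, isomir_rate = 0.2,
                       isomir_other_rate = 0.05, snv_rate = 0.1,
                       base_phred = 35L, degrade_position = NULL,
                       degrade_phred = 20L) {
  stopifnot(
    n_reads >= 0, read_length >= 1,
    isomir_rate >= 0, isomir_rate <= 1,
    isomir_other_rate >= 0, isomir_other_rate <= 1,
    snv_rate >= 0, snv_rate <= 1,
    nchar(adapter) >= 8
  )
  structure(
    list(
      n_reads = as.integer(n_reads), seed = as.integer(seed),
      adapter = adapter, read_length = as.integer(read_length),
      isomir_rate = isomir_rate, isomir_other_rate = isomir_other_rate,
      snv_rate = snv_rate, base_phred = as.integer(base_phred),
      degrade_position = degrade_position, degrade_phred = as.integer(degrade_phred)
    ),
    class = "mirsat_sim_config"
  )
}

# substitute one random base (never the original) at a uniform position of
# each string in `x`; returns list(seq, label)
apply_snv <- function(x) {
  n <- length(x)
  if (n == 0L) return(list(seq = x, label = character(0)))
  len <- nchar(x)
  pos <- 1L + floor(runif(n) * len)
  old <- substr(x, pos, pos)
  old_idx <- match(old, DNA_BASES)
  new_idx <- ((old_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  new <- DNA_BASES[new_idx]
  substr(x, pos, pos) <- new
  list(seq = x, label = sprintf("s%d%s", pos, new))
}

#' Simulate one small RNA sequencing library
#'
#' Draws `cfg$n_reads` reads from the six generator categories (mature miRNA,
#' structured ncRNA, repeat, unclassified, out-of-tolerance isomiR, adapter
#' dimer), assembles each as insert + adapter + random padding truncated to
#' `read_length` cycles, and returns the reads together with a per-read truth
#' ledger. Adapter-dimer reads begin with the adapter at position 0; all
#' other reads begin with their insert. miRNA-category reads may carry an
#' in-tolerance 3' isomiR edit and/or one substitution error; decoy-category
#' reads are exact pool sequences.
#'
#' @param ref Mature reference (`build_reference()`).
#' @param profile Abundance profile (`simulate_abundances()`).
#' @param comp Composition profile (`composition_muscle()` etc.).
#' @param cfg Simulation config (`sim_config()`).
#' @param decoys Decoy pools for the same reference (`decoy_pools()`).
#' @param fastq_path,ledger_path Optional output files (FASTQ phred+33 and
#'   TSV ledger).
#' @return List of class `mirsat_library` with elements `reads` (read set),
#'   `ledger` (tibble: `read_id`, `category`, `source_id`, `edits`,
#'   `insert`) and `config`.
#' @export
simulate_library <- function(ref, profile, comp, cfg, decoys,
                             fastq_path = NULL, ledger_path = NULL) {
  stopifnot(inherits(cfg, "mirsat_sim_config"), inherits(comp, "mirsat_composition"))
  ids <- names(profile)
  if (!all(ids %in% ref$mirna_id)) {
    stop_mirsat("abundance profile names miRNAs absent from the reference", "mirsat_bad_profile")
  }
  if (abs(sum(profile) - 1) > 1e-9) {
    stop_mirsat("abundance weights must sum to 1", "mirsat_bad_profile")
  }
  ref_seq <- ref$sequence[match(ids, ref$mirna_id)]
  shortest_insert <- min(nchar(ref_seq)) - 2L
  if (cfg$read_length < shortest_insert + 1L) {
    stop_mirsat("read_length is shorter than the shortest insert + 1", "mirsat_bad_read_length")
  }
  n <- cfg$n_reads
  adapter <- cfg$adapter
  seed_pat <- substr(adapter, 1L, 8L)

  # six-way category probabilities: the out-of-tolerance isomiR slice is
  # carved from the unclassified budget (see vignette)
  slice <- cfg$isomir_other_rate * (1 - comp[["adapter_dimer"]])
  if (slice > comp[["unclassified"]] + 1e-12) {
    stop_mirsat("isomir_other_rate exceeds the unclassified budget", "mirsat_bad_composition")
  }
  p6 <- c(
    mirna = comp[["mirna"]], ncrna = comp[["ncrna"]], "repeat" = comp[["repeat"]],
    unclassified = comp[["unclassified"]] - slice, isomir_other = slice,
    adapter_dimer = comp[["adapter_dimer"]]
  )

  empty <- function() {
    list(
      reads = read_set(character(0), character(0), character(0)),
      ledger = tibble::tibble(
        read_id = character(0), category = character(0),
        source_id = character(0), edits = character(0), insert = character(0)
      ),
      config = cfg
    )
  }
  if (n == 0L) {
    out <- structure(empty(), class = "mirsat_library")
    if (!is.null(fastq_path)) write_fastq(out$reads, fastq_path)
    if (!is.null(ledger_path)) write_ledger(out$ledger, ledger_path)
    return(out)
  }

  out <- with_seed(cfg$seed, {
    cat_idx <- sample.int(6L, n, replace = TRUE, prob = p6)
    category <- names(p6)[cat_idx]
    insert <- character(n)
    source_id <- rep(NA_character_, n)
    edits <- character(n)

    ## mature miRNA reads: abundance-weighted source, optional in-tolerance
    ## 3' edit, optional single substitution
    im <- which(cat_idx == 1L)
    if (length(im)) {
      src <- sample.int(length(ids), length(im), replace = TRUE, prob = profile)
      s <- ref_seq[src]
      lab <- character(length(im))
      iso <- runif(length(im)) < cfg$isomir_rate
      if (any(iso)) {
        ty <- sample(c("t1", "t2", "e1", "e2"), sum(iso), replace = TRUE)
        si <- s[iso]
        L <- nchar(si)
        tr <- ty %in% c("t1", "t2")
        ntrim <- ifelse(ty == "t1", 1L, 2L)
        si[tr] <- substr(si[tr], 1L, L[tr] - ntrim[tr])
        ex <- !tr
        next_ <- ifelse(ty == "e1", 1L, 2L)
        if (any(ex)) si[ex] <- paste0(si[ex], rand_dna(sum(ex), next_[ex]))
        s[iso] <- si
        lab[iso] <- ty
      }
      snv <- runif(length(im)) < cfg$snv_rate
      if (any(snv)) {
        sub <- apply_snv(s[snv])
        s[snv] <- sub$seq
        lab[snv] <- paste0(lab[snv], ifelse(nzchar(lab[snv]), ";", ""), sub$label)
      }
      # an edit must never create an adapter-seed substring inside the insert
      # (it would shift the clip point); such reads revert to the unedited
      # reference sequence
      bad <- contains_fixed(s, seed_pat)
      if (any(bad)) {
        s[bad] <- ref_seq[src][bad]
        lab[bad] <- ""
      }
      insert[im] <- s
      source_id[im] <- ids[src]
      edits[im] <- lab
    }

    ## out-of-tolerance isomiRs: 3' extension of 3-5 nt, or a 3-nt trim when
    ## the source stays >= 18 nt
    io <- which(cat_idx == 5L)
    if (length(io)) {
      src <- sample.int(length(ids), length(io), replace = TRUE, prob = profile)
      s0 <- ref_seq[src]
      ty <- sample(c("e3", "e4", "e5", "t3"), length(io), replace = TRUE)
      ty[ty == "t3" & nchar(s0) - 3L < 18L] <- "e3"
      s <- s0
      tr <- ty == "t3"
      s[tr] <- substr(s[tr], 1L, nchar(s[tr]) - 3L)
      ex <- !tr
      nex <- as.integer(substr(ty, 2L, 2L))
      iter <- 0L
      while (any(ex) && iter < 25L) {
        s[ex] <- paste0(s0[ex], rand_dna(sum(ex), nex[ex]))
        ex <- ex & contains_fixed(s, seed_pat) # redraw seed-creating extensions
        iter <- iter + 1L
      }
      insert[io] <- s
      source_id[io] <- ids[src]
      edits[io] <- ty
    }

    ## decoy categories: exact pool sequences
    for (cat in c("ncrna", "repeat", "unclassified")) {
      ic <- which(category == cat)
      if (!length(ic)) next
      pool <- decoys[[cat]]
      if (is.null(pool) || nrow(pool) == 0L) {
        stop_mirsat(sprintf("no decoy pool for category '%s'", cat), "mirsat_missing_decoys")
      }
      pick <- sample.int(nrow(pool), length(ic), replace = TRUE)
      insert[ic] <- pool$sequence[pick]
      source_id[ic] <- pool$source_id[pick]
    }

    ## adapter dimers: adapter at position 0
    idm <- which(cat_idx == 6L)
    if (length(idm)) {
      dimer <- substr(strrep(adapter, ceiling(cfg$read_length / nchar(adapter)) + 1L),
                      1L, cfg$read_length)
      insert[idm] <- ""
      source_id[idm] <- "adapter"
    }

    ## assemble: insert + adapter + random padding, truncated to read_length
    full <- paste0(insert, adapter)
    pad_needed <- pmax(0L, cfg$read_length - nchar(full))
    pad <- character(n)
    np <- pad_needed > 0L
    if (any(np)) pad[np] <- rand_dna(sum(np), pad_needed[np])
    sequence <- substr(paste0(full, pad), 1L, cfg$read_length)
    if (length(idm)) {
      sequence[idm] <- substr(strrep(adapter, ceiling(cfg$read_length / nchar(adapter)) + 1L),
                              1L, cfg$read_length)
    }

    qual1 <- strrep(rawToChar(as.raw(33L + cfg$base_phred)), cfg$read_length)
    if (!is.null(cfg$degrade_position)) {
      p <- as.integer(cfg$degrade_position)
      substr(qual1, p, p) <- rawToChar(as.raw(33L + cfg$degrade_phred))
    }
    quality <- rep(qual1, n)

    read_id <- sprintf("r%07d", seq_len(n))
    list(
      reads = read_set(read_id, sequence, quality),
      ledger = tibble::tibble(
        read_id = read_id, category = category,
        source_id = source_id, edits = edits, insert = insert
      ),
      config = cfg
    )
  })
  out <- structure(out, class = "mirsat_library")
  if (!is.null(fastq_path)) write_fastq(out$reads, fastq_path)
  if (!is.null(ledger_path)) write_ledger(out$ledger, ledger_path)
  out
}

#' Ground truth for a two-group experiment
#'
#' @param ref Mature reference.
#' @param log2fc Named numeric vector of injected log2 fold changes
#'   (group 2 vs group 1); miRNAs not named have true log2FC 0. Naming a
#'   miRNA absent from the reference is an error.
#' @param phi Common overdispersion of replicate counts (gamma-mixed Poisson;
#'   0 gives pure Poisson noise).
#' @param n_per_group Replicates per group (default 9, the study design).
#' @return List of class `mirsat_truth`: `table` (tibble `mirna_id`,
#'   `log2fc`, `is_de`), `phi`, `n_per_group`.
#' @export
experiment_truth <- function(ref, log2fc = numeric(0), phi = 0.1, n_per_group = 9L) {
  stopifnot(phi >= 0, n_per_group >= 2)
  if (length(log2fc) && (is.null(names(log2fc)) || !all(names(log2fc) %in% ref$mirna_id))) {
    stop_mirsat("log2fc names a miRNA absent from the reference", "mirsat_bad_truth")
  }
  fc <- setNames(numeric(nrow(ref)), ref$mirna_id)
  fc[names(log2fc)] <- log2fc
  structure(
    list(
      table = tibble::tibble(mirna_id = ref$mirna_id, log2fc = unname(fc), is_de = fc != 0),
      phi = phi, n_per_group = as.integer(n_per_group)
    ),
    class = "mirsat_truth"
  )
}

# expected per-group abundance profiles: group 2 = baseline * 2^log2fc,
# renormalized
group_profiles <- function(profile, truth) {
  fc <- setNames(truth$table$log2fc, truth$table$mirna_id)[names(profile)]
  w2 <- as.numeric(profile) * 2^fc
  list(
    g1 = setNames(as.numeric(profile), names(profile)),
    g2 = setNames(w2 / sum(w2), names(profile))
  )
}

#' Simulate a full two-group experiment as FASTQ-level libraries
#'
#' Emits `2 * n_per_group` libraries. Group-2 expected abundances are the
#' baseline scaled by `2^log2fc` and renormalized; per-replicate biological
#' noise is injected by jittering each miRNA's weight with a mean-1 gamma
#' variable of shape `1/phi` (gamma-mixed Poisson overdispersion). Each
#' library draws its seed from the global seed by a stable hash of its index,
#' so any library can be regenerated in isolation.
#'
#' @inheritParams simulate_library
#' @param truth `experiment_truth()` object.
#' @return List of class `mirsat_experiment`: `libraries` (named list of
#'   `mirsat_library`), `groups` (factor), `truth`.
#' @export
simulate_experiment <- function(ref, profile, comp, truth, cfg, decoys) {
  stopifnot(inherits(truth, "mirsat_truth"))
  n <- truth$n_per_group
  gp <- group_profiles(profile, truth)
  sample_ids <- c(sprintf("g1_r%d", seq_len(n)), sprintf("g2_r%d", seq_len(n)))
  groups <- factor(rep(c("g1", "g2"), each = n))
  libs <- vector("list", 2L * n)
  names(libs) <- sample_ids
  for (k in seq_len(2L * n)) {
    w <- if (k <= n) gp$g1 else gp$g2
    if (truth$phi > 0) {
      g <- with_seed(derive_seed(cfg$seed, 100000L + k), {
        rgamma(length(w), shape = 1 / truth$phi, rate = 1 / truth$phi)
      })
      w <- w * g
      w <- w / sum(w)
    }
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, k)
    libs[[k]] <- simulate_library(ref, structure(w, class = "mirsat_abundance"),
                                  comp, cfg_k, decoys)
  }
  structure(
    list(libraries = libs, groups = groups, truth = truth),
    class = "mirsat_experiment"
  )
}

#' Simulate a two-group experiment directly at the count level
#'
#' The count-level twin of [simulate_experiment()]: per-miRNA counts are
#' drawn as negative binomial with mean `weight * depth` and dispersion
#' `truth$phi` (Poisson when `phi = 0`), skipping read assembly and
#' quantification. Used for differential-expression calibration studies
#' where only the count matrix matters.
#'
#' @param ref Mature reference.
#' @param profile Baseline abundance profile.
#' @param truth `experiment_truth()` object.
#' @param depth Expected mapped reads per library (scalar or per-library
#'   vector of length `2 * n_per_group`).
#' @param seed Integer seed.
#' @return List: `counts` (matrix miRNA x sample), `groups`, `truth`.
#' @export
simulate_experiment_counts <- function(ref, profile, truth, depth, seed = 1L) {
  stopifnot(inherits(truth, "mirsat_truth"))
  n <- truth$n_per_group
  depth <- rep_len(depth, 2L * n)
  gp <- group_profiles(profile, truth)
  mu <- cbind(
    matrix(gp$g1, ncol = n, nrow = length(profile)),
    matrix(gp$g2, ncol = n, nrow = length(profile))
  )
  mu <- sweep(mu, 2L, depth, `*`)
  counts <- with_seed(seed, {
    if (truth$phi > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / truth$phi), nrow = nrow(mu))
    } else {
      matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu))
    }
  })
  rownames(counts) <- names(profile)
  colnames(counts) <- c(sprintf("g1_r%d", seq_len(n)), sprintf("g2_r%d", seq_len(n)))
  list(
    counts = counts,
    groups = factor(rep(c("g1", "g2"), each = n)),
    truth = truth
  )
}

#' Simulate a pool of mapped reads as a collapsed read set
#'
#' Draws `n` mapped reads multinomially from the abundance profile and
#' returns them as a collapsed read set of exact mature sequences, the input
#' expected by the saturation and correlation resampling procedures.
#'
#' @param ref Mature reference.
#' @param profile Abundance profile.
#' @param n Total mapped reads.
#' @param seed Integer seed.
#' @return Collapsed read set (`sequence`, `count`) with the source miRNA id
#'   in attribute `source_id`.
#' @export
simulate_mapped_pool <- function(ref, profile, n, seed = 1L) {
  counts <- with_seed(seed, as.integer(stats::rmultinom(1L, n, prob = profile)))
  keep <- counts > 0L
  seqs <- ref$sequence[match(names(profile), ref$mirna_id)]
  out <- tibble::tibble(sequence = seqs[keep], count = counts[keep])
  attr(out, "source_id") <- names(profile)[keep]
  attr(out, "total") <- sum(counts)
  class(out) <- c("mirsat_collapsed", class(out))
  out
}
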