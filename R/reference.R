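ILLUMINA_3P_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Validate and construct a mature miRNA reference
#'
#' A reference is a tibble with columns `mirna_id` and `sequence`
#' (DNA alphabet, 18-25 nt). Ids must be unique and no sequence may
#' duplicate another entry's sequence.
#'
#' @param entries Tibble or data frame with `mirna_id`, `sequence`.
#' @return The validated reference tibble, class `mirsat_reference`.
#' @export
mature_reference <- function(entries) {
  entries <- tibble::as_tibble(entries)[, c("mirna_id", "sequence")]
  if (nrow(entries) == 0L) {
    stop_mirsat("a mature reference must have at least one entry", "mirsat_empty_reference")
  }
  if (anyDuplicated(entries$mirna_id)) {
    stop_mirsat("reference ids must be unique", "mirsat_bad_reference")
  }
  if (any(!nzchar(entries$sequence))) {
    stop_mirsat("reference sequences must be non-empty", "mirsat_bad_reference")
  }
  if (anyDuplicated(entries$sequence)) {
    stop_mirsat("reference contains duplicated sequences", "mirsat_bad_reference")
  }
  if (any(grepl("[^ACGT]", entries$sequence))) {
    stop_mirsat("reference sequences must be over {A,C,G,T}", "mirsat_bad_reference")
  }
  class(entries) <- c("mirsat_reference", class(entries))
  entries
}

#' Build a synthetic mature miRNA reference
#'
#' Generates `n_mirnas` random mature sequences (ids `syn-miR-NNN`) with two
#' guarantees that make downstream truth unambiguous: (i) any two sequences of
#' the same length differ at >= `min_separation` positions, so single-SNV
#' assignment can never be confused between equal-length entries; and (ii) no
#' sequence contains the adapter's seed prefix, so adapter clipping can never
#' truncate a genuine insert.
#'
#' The default length range 20-23 nt covers the typical mature miRNA lengths
#' and guarantees that a 2-nt 3' trim never drops a read below the 18-nt
#' length filter.
#'
#' @param n_mirnas Number of entries (>= 1).
#' @param length_range Integer pair within 18-25.
#' @param seed Integer seed; fixed seed gives an identical reference.
#' @param min_separation Minimum pairwise Hamming distance between
#'   equal-length sequences (default 3).
#' @param adapter Adapter whose 8-nt seed is excluded from all sequences.
#' @return A `mirsat_reference` tibble.
#' @export
build_reference <- function(n_mirnas, length_range = c(20L, 23L), seed = 1L,
                            min_separation = 3L,
                            adapter = ILLUMINA_3P_ADAPTER) {
  stopifnot(n_mirnas >= 1, length(length_range) == 2L)
  length_range <- as.integer(sort(length_range))
  if (length_range[1] < 18L || length_range[2] > 25L) {
    stop_mirsat("reference lengths must lie within 18-25 nt", "mirsat_bad_length_range")
  }
  seed_pat <- substr(adapter, 1L, 8L)
  with_seed(seed, {
    vals <- seq(length_range[1], length_range[2])
    lens <- vals[sample.int(length(vals), n_mirnas, replace = TRUE)]
    seqs <- character(n_mirnas)
    # accepted sequences per length, as raw matrices for fast one-vs-many
    # Hamming checks
    acc <- list()
    attempts <- 0L
    max_attempts <- 200L * n_mirnas + 1000L
    for (i in seq_len(n_mirnas)) {
      L <- lens[i]
      key <- as.character(L)
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop_mirsat(
            sprintf(
              "could not build %d sequences at pairwise Hamming >= %d within lengths %d-%d",
              n_mirnas, min_separation, length_range[1], length_range[2]
            ),
            "mirsat_reference_separation"
          )
        }
        cand <- rand_dna(1L, L)
        if (contains_fixed(cand, seed_pat)) next
        m <- acc[[key]]
        if (!is.null(m)) {
          d <- colSums(m != charToRaw(cand))
          if (any(d < min_separation)) next
        }
        seqs[i] <- cand
        acc[[key]] <- cbind(m, charToRaw(cand))
        break
      }
    }
    mature_reference(tibble::tibble(
      mirna_id = sprintf("syn-miR-%0*d", max(3L, nchar(n_mirnas)), seq_len(n_mirnas)),
      sequence = seqs
    ))
  })
}

#' Simulate a long-tailed miRNA abundance profile
#'
#' Per-miRNA relative abundances drawn from a log-normal law (default) or a
#' power law. The log-normal default (`shape` = sigma on the log scale) is
#' chosen to reproduce the strongly skewed expression profiles seen in real
#' small RNA libraries: a handful of miRNAs carry most of the mass while a
#' long tail of rare miRNAs saturates detection only slowly with depth.
#'
#' @param ref Mature reference.
#' @param shape Positive shape: log-normal sigma, or power-law exponent when
#'   `law = "powerlaw"`.
#' @param seed Integer seed.
#' @param law `"lognormal"` (default) or `"powerlaw"` (weight of rank r
#'   proportional to `r^-shape`).
#' @return Named numeric vector of weights summing to 1, class
#'   `mirsat_abundance`.
#' @export
simulate_abundances <- function(ref, shape = 3, seed = 1L,
                                law = c("lognormal", "powerlaw")) {
  law <- match.arg(law)
  if (nrow(ref) == 0L) stop_mirsat("empty reference", "mirsat_empty_reference")
  stopifnot(shape > 0)
  w <- with_seed(seed, {
    n <- nrow(ref)
    if (law == "lognormal") {
      exp(rnorm(n, 0, shape))
    } else {
      sample(seq_len(n))^(-shape)
    }
  })
  w <- w / sum(w)
  structure(setNames(w, ref$mirna_id), class = "mirsat_abundance")
}

#' Library composition profile
#'
#' Fractions of all sequenced reads falling in each category:
#' mature miRNA, structured ncRNA (Rfam-like), repeat (RepBase-like),
#' unclassified, and adapter dimer. Fractions must sum to 1.
#'
#' `composition_muscle()` and `composition_plasma()` build the two default
#' tissue profiles from the category percentages observed among
#' *post-clipped* reads (muscle: 68% mature / 7% ncRNA / 3% repeat;
#' plasma: 21% / 25% / 0.21%), scaling by `1 - dimer` so that after
#' adapter-only reads are removed the post-clipped expectations equal those
#' percentages. The dimer fractions (5% muscle, 15% plasma) reflect that
#' low-RNA plasma preps carry substantially more adapter-dimer contamination;
#' no measured dimer fraction is available, so these are engineering choices.
#'
#' @param f_mirna,f_ncrna,f_repeat,f_unclassified,f_adapter_dimer Fractions
#'   in `[0,1]` summing to 1 (within 1e-9).
#' @return Named numeric vector of class `mirsat_composition`.
#' @export
composition_profile <- function(f_mirna, f_ncrna, f_repeat, f_unclassified,
                                f_adapter_dimer) {
  p <- c(
    mirna = f_mirna, ncrna = f_ncrna, rep = f_repeat,
    unclassified = f_unclassified, adapter_dimer = f_adapter_dimer
  )
  names(p)[3] <- "repeat"
  if (any(p < 0) || any(p > 1)) {
    stop_mirsat("composition fractions must lie in [0,1]", "mirsat_bad_composition")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_mirsat("composition fractions must sum to 1", "mirsat_bad_composition")
  }
  structure(p, class = "mirsat_composition")
}

#' @param mirna,ncrna,rep Target category fractions among post-clipped reads.
#' @param dimer Adapter-dimer fraction of all reads.
#' @rdname composition_profile
#' @export
composition_muscle <- function(mirna = 0.68, ncrna = 0.07, rep = 0.03,
                               dimer = 0.05) {
  uncl <- 1 - mirna - ncrna - rep
  if (uncl < 0) stop_mirsat("post-clip fractions exceed 1", "mirsat_bad_composition")
  s <- 1 - dimer
  composition_profile(mirna * s, ncrna * s, rep * s, uncl * s, dimer)
}

#' @rdname composition_profile
#' @export
composition_plasma <- function(mirna = 0.21, ncrna = 0.25, rep = 0.0021,
                               dimer = 0.15) {
  composition_muscle(mirna, ncrna, rep, dimer)
}

#' Generate category decoy pools for a reference
#'
#' Builds the fixed sequence pools that non-miRNA reads are drawn from:
#' structured-ncRNA fragments (28-40 nt), repeat fragments (28-40 nt) and
#' unclassified sequences (18-30 nt). Pools are generated once per reference
#' with a guaranteed margin of >= 3 mismatches over the first 16 nt against
#' every mature sequence (and no adapter seed substring), so category truth
#' stays unambiguous even under the quantifier's 1-SNV tolerance. The ncRNA
#' and repeat lengths exceed the longest mature-plus-window read on purpose:
#' a structured-RNA fragment can then never be length-compatible with a
#' mature assignment.
#'
#' @param ref Mature reference.
#' @param seed Integer seed.
#' @param n_each Named integer vector of pool sizes.
#' @param adapter Adapter whose seed is excluded.
#' @return List of tibbles (`ncrna`, `repeat`, `unclassified`), each with
#'   `source_id`, `sequence`.
#' @export
decoy_pools <- function(ref, seed = 1L,
                        n_each = c(ncrna = 300L, "repeat" = 150L, unclassified = 400L),
                        adapter = ILLUMINA_3P_ADAPTER) {
  seed_pat <- substr(adapter, 1L, 8L)
  ref16 <- substr(ref$sequence, 1L, 16L)
  lens <- list(
    ncrna = c(28L, 40L), "repeat" = c(28L, 40L), unclassified = c(18L, 30L)
  )
  prefix <- c(ncrna = "ncR", "repeat" = "rep", unclassified = "unc")
  with_seed(seed, {
    out <- lapply(names(lens), function(cat) {
      n <- n_each[[cat]]
      lr <- lens[[cat]]
      seqs <- character(0)
      while (length(seqs) < n) {
        need <- n - length(seqs)
        lvals <- seq(lr[1], lr[2])
        cand <- rand_dna(2L * need, lvals[sample.int(length(lvals), 2L * need, replace = TRUE)])
        ok <- !contains_fixed(cand, seed_pat)
        # >= 3 mismatches over the first 16 nt against every mature sequence
        cand16 <- substr(cand, 1L, 16L)
        near <- vapply(cand16, function(s) {
          any(hamming_overlap(rep(s, length(ref16)), ref16) < 3L)
        }, logical(1))
        keep <- cand[ok & !near]
        seqs <- unique(c(seqs, keep))
      }
      seqs <- seqs[seq_len(n)]
      tibble::tibble(
        source_id = sprintf("%s-%04d", prefix[[cat]], seq_len(n)),
        sequence = seqs
      )
    })
    names(out) <- names(lens)
    # pools must not collide with each other (exact-match classification)
    all_seq <- unlist(lapply(out, `[[`, "sequence"))
    if (anyDuplicated(all_seq)) {
      dup <- duplicated(all_seq)
      for (cat in names(out)) {
        out[[cat]] <- out[[cat]][!out[[cat]]$sequence %in% all_seq[dup], ]
      }
    }
    out
  })
}
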