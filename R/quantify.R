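#' Classify unique post-clipped sequences against a mature reference
#'
#' The single-SNV matcher at the core of quantification. A sequence is
#' assigned `mature` to reference `i` when a 5'-anchored comparison shows at
#' most `max_snv` substitutions over the overlap (the shorter of the two
#' lengths) and the 3' length difference is within
#' `+/- three_prime_window` nt. A sequence whose 5' anchor holds (at most
#' `max_snv` substitutions over the first 16 nt) but which fails the 3'
#' window or the full-overlap budget is an out-of-tolerance isomiR and goes
#' to the `others_isomir` ledger. Remaining sequences are looked up
#' (exactly) in the ncRNA and repeat decoy references, and otherwise left
#' `unclassified`.
#'
#' Candidate generation is exact by pigeonhole: a sequence within one
#' substitution of a reference over its first 16 nt must match the
#' reference's first or second 8-mer exactly, so hashing both 8-mers finds
#' every admissible candidate.
#'
#' @param sequences Character vector of unique sequences (each >= 18 nt).
#' @param ref Mature reference.
#' @param decoys Optional decoy pools (`decoy_pools()`).
#' @param max_snv Substitution budget (default 1).
#' @param three_prime_window Tolerated 3' length difference in nt for a
#'   mature call (default 2).
#' @return Tibble: `sequence`, `category` (mature / others_isomir / ncrna /
#'   repeat / unclassified), `mirna_id` (best match or source id),
#'   `candidates` (list column of tied mature candidate ids),
#'   `n_mismatches`, `three_prime_offset`.
#' @export
classify_sequences <- function(sequences, ref, decoys = NULL, max_snv = 1L,
                               three_prime_window = 2L) {
  ref <- mature_reference(ref)
  stopifnot(all(nchar(sequences) >= 18L))
  n <- length(sequences)
  out <- tibble::tibble(
    sequence = sequences,
    category = rep("unclassified", n),
    mirna_id = rep(NA_character_, n),
    candidates = vector("list", n),
    n_mismatches = rep(NA_integer_, n),
    three_prime_offset = rep(NA_integer_, n)
  )
  if (n == 0L) return(out)

  reads <- tibble::tibble(
    sid = seq_len(n), seq = sequences,
    k1 = substr(sequences, 1L, 8L), k2 = substr(sequences, 9L, 16L)
  )
  refs <- tibble::tibble(
    mirna_id = ref$mirna_id, rseq = ref$sequence,
    k1 = substr(ref$sequence, 1L, 8L), k2 = substr(ref$sequence, 9L, 16L)
  )
  pairs <- dplyr::bind_rows(
    dplyr::inner_join(reads[c("sid", "seq", "k1")], refs[c("mirna_id", "rseq", "k1")],
                      by = "k1", relationship = "many-to-many"),
    dplyr::inner_join(reads[c("sid", "seq", "k2")], refs[c("mirna_id", "rseq", "k2")],
                      by = "k2", relationship = "many-to-many")
  )
  pairs <- dplyr::distinct(pairs[c("sid", "seq", "mirna_id", "rseq")])

  if (nrow(pairs)) {
    pairs$mm16 <- hamming_overlap(pairs$seq, pairs$rseq, cap = 16L)
    pairs$mm <- hamming_overlap(pairs$seq, pairs$rseq)
    pairs$dlen <- nchar(pairs$seq) - nchar(pairs$rseq)
    pairs$mature <- pairs$mm <= max_snv & abs(pairs$dlen) <= three_prime_window
    pairs$anchor <- pairs$mm16 <= max_snv

    mat <- pairs[pairs$mature, ]
    if (nrow(mat)) {
      mat <- mat[order(mat$sid, mat$mm, abs(mat$dlen), mat$mirna_id), ]
      best <- mat[!duplicated(mat$sid), ]
      out$category[best$sid] <- "mature"
      out$mirna_id[best$sid] <- best$mirna_id
      out$n_mismatches[best$sid] <- best$mm
      out$three_prime_offset[best$sid] <- best$dlen
      out$candidates[unique(mat$sid)] <- split(mat$mirna_id, mat$sid)
    }

    oth <- pairs[pairs$anchor & !pairs$mature, ]
    oth <- oth[!(oth$sid %in% mat$sid), ]
    if (nrow(oth)) {
      oth <- oth[order(oth$sid, oth$mm16, abs(oth$dlen), oth$mirna_id), ]
      best <- oth[!duplicated(oth$sid), ]
      out$category[best$sid] <- "others_isomir"
      out$mirna_id[best$sid] <- best$mirna_id
      out$n_mismatches[best$sid] <- best$mm16
      out$three_prime_offset[best$sid] <- best$dlen
    }
  }

  if (!is.null(decoys)) {
    open <- out$category == "unclassified"
    for (cat in c("ncrna", "repeat")) {
      pool <- decoys[[cat]]
      if (is.null(pool)) next
      hit <- match(out$sequence, pool$sequence)
      take <- open & !is.na(hit)
      out$category[take] <- cat
      out$mirna_id[take] <- pool$source_id[hit[take]]
      open <- open & !take
    }
  }
  out
}

#' Assign one read sequence to the reference
#'
#' Single-sequence interface to [classify_sequences()].
#'
#' @inheritParams classify_sequences
#' @param sequence One sequence of length >= 18.
#' @return One-row assignment tibble.
#' @export
align_read <- function(sequence, ref, decoys = NULL, max_snv = 1L,
                       three_prime_window = 2L) {
  stopifnot(length(sequence) == 1L)
  if (nchar(sequence) < 18L) {
    stop_mirsat("align_read requires a sequence of length >= 18", "mirsat_short_sequence")
  }
  classify_sequences(sequence, ref, decoys, max_snv, three_prime_window)
}

#' Distribute multi-mapping reads over candidate miRNAs
#'
#' @param assignments Tibble with list column `candidates` (>= 1 candidate
#'   id per row) and a `count` multiplicity column.
#' @param all_ids Character vector of every miRNA id (output support).
#' @param policy `"uniform"` (default: 1/k of each read's mass to each of
#'   its k candidates), `"em"` (iterative redistribution proportional to
#'   current abundance estimates, the Seq-EM idea), or `"discard"`
#'   (multi-candidate reads contribute nothing).
#' @param tol EM convergence: maximum absolute change in any allocated
#'   count (default 1e-8).
#' @param max_iter EM iteration cap (default 500).
#' @return Named numeric vector of per-miRNA counts over `all_ids`. Under
#'   `uniform` and `em` the total allocated mass equals the total read
#'   multiplicity.
#' @export
resolve_multimappers <- function(assignments, all_ids,
                                 policy = c("uniform", "em", "discard"),
                                 tol = 1e-8, max_iter = 500L) {
  policy <- match.arg(policy)
  counts <- setNames(numeric(length(all_ids)), all_ids)
  if (nrow(assignments) == 0L) return(counts)
  k <- lengths(assignments$candidates)
  if (any(k < 1L)) {
    stop_mirsat("every assignment must list at least one candidate id", "mirsat_bad_assignment")
  }
  long <- tibble::tibble(
    row = rep(seq_len(nrow(assignments)), k),
    mirna_id = unlist(assignments$candidates),
    mult = rep(assignments$count, k),
    k = rep(k, k)
  )
  add <- function(ids, w) {
    s <- rowsum(w, ids)
    counts[rownames(s)] <- counts[rownames(s)] + as.numeric(s)
    counts
  }
  if (policy == "discard") {
    u <- long[long$k == 1L, ]
    return(add(u$mirna_id, u$mult))
  }
  if (policy == "uniform") {
    return(add(long$mirna_id, long$mult / long$k))
  }
  # em: unique reads anchor the abundances; shared reads are split in
  # proportion to the current estimates
  uniq <- long[long$k == 1L, ]
  shared <- long[long$k > 1L, ]
  base <- setNames(numeric(length(all_ids)), all_ids)
  if (nrow(uniq)) {
    s <- rowsum(uniq$mult, uniq$mirna_id)
    base[rownames(s)] <- as.numeric(s)
  }
  if (nrow(shared) == 0L) return(counts + base)
  est <- base
  est[est == 0] <- 0 # ids without unique evidence start at zero
  prev <- NULL
  for (it in seq_len(max_iter)) {
    p <- est[shared$mirna_id]
    denom <- as.numeric(rowsum(p, shared$row)[as.character(shared$row), 1L])
    w <- ifelse(denom > 0, p / denom, 1 / shared$k) # uniform fallback where
    # no candidate has any unique evidence (logged below)
    alloc <- setNames(numeric(length(all_ids)), all_ids)
    s <- rowsum(shared$mult * w, shared$mirna_id)
    alloc[rownames(s)] <- as.numeric(s)
    est_new <- base + alloc
    if (!is.null(prev) && max(abs(est_new - prev)) < tol) {
      est <- est_new
      break
    }
    prev <- est_new
    est <- est_new
  }
  if (any(tapply(base[shared$mirna_id], shared$row, sum) == 0)) {
    message("resolve_multimappers: component(s) without uniquely mapping reads; uniform split used there")
  }
  counts + est
}

#' Reads-per-million normalization
#'
#' `RPM_i = count_i / library_size * 1e6`.
#'
#' @param counts Non-negative count vector (may be fractional after
#'   multimapper redistribution).
#' @param library_size Positive total used as the denominator.
#' @return Numeric RPM vector, same names as `counts`.
#' @export
compute_rpm <- function(counts, library_size) {
  if (length(library_size) != 1L || !is.finite(library_size) || library_size <= 0) {
    stop_mirsat("library_size must be a single positive number", "mirsat_bad_library_size")
  }
  if (any(counts < 0)) stop_mirsat("counts must be non-negative", "mirsat_bad_counts")
  counts / library_size * 1e6
}

#' Detection set at a read-count threshold
#'
#' @param counts Named per-miRNA count vector.
#' @param threshold Minimum count for detection (>= 1).
#' @return Character vector of detected miRNA ids (monotone decreasing in
#'   `threshold`).
#' @export
detection_set <- function(counts, threshold = 1) {
  stopifnot(threshold >= 1)
  names(counts)[counts >= threshold]
}

#' Library composition breakdown over post-clipped reads
#'
#' Fractions of post-clipped reads per category. The mature-mapped fraction
#' excludes `others_isomir` reads, which are folded into `unclassified` for
#' the four-way breakdown (they are not counted as mapped) and additionally
#' reported on their own.
#'
#' @param assignments Classification tibble ([classify_sequences()]).
#' @param multiplicities Per-sequence read multiplicities (default 1 each).
#' @return List of class `mirsat_composition_report`: `fractions` (named:
#'   mature, ncrna, repeat, unclassified; sums to 1), `others_isomir`
#'   (fraction, subset of unclassified), `n_reads`.
#' @export
composition_breakdown <- function(assignments, multiplicities = NULL) {
  m <- multiplicities %||% rep(1, nrow(assignments))
  total <- sum(m)
  frac_of <- function(cat) sum(m[assignments$category %in% cat]) / total
  fr <- c(
    mature = frac_of("mature"),
    ncrna = frac_of("ncrna"),
    "repeat" = frac_of("repeat"),
    unclassified = frac_of(c("unclassified", "others_isomir"))
  )
  structure(
    list(
      fractions = fr,
      others_isomir = frac_of("others_isomir"),
      n_reads = total
    ),
    class = "mirsat_composition_report"
  )
}

#' Quantify one preprocessed sample
#'
#' Classifies the collapsed post-clipped sequences, resolves multi-mapping
#' mature reads under the chosen policy, and tallies mature counts, the
#' isomiR "others" ledger, RPM and the composition breakdown. The library
#' size is the mapped total (reads assigned mature).
#'
#' @inheritParams classify_sequences
#' @param collapsed Collapsed read set (`sequence`, `count`).
#' @param policy Multimapper policy, see [resolve_multimappers()].
#' @return List of class `mirsat_quant`: `counts` (named, over all reference
#'   ids), `rpm`, `others_counts` (named per source miRNA), `composition`,
#'   `library_size` (mapped total), `n_postclipped`, `assignments`.
#' @export
quantify_sample <- function(collapsed, ref, decoys = NULL, max_snv = 1L,
                            three_prime_window = 2L,
                            policy = c("uniform", "em", "discard")) {
  policy <- match.arg(policy)
  cls <- classify_sequences(collapsed$sequence, ref, decoys, max_snv, three_prime_window)
  cls$count <- collapsed$count
  mat <- cls[cls$category == "mature", c("candidates", "count")]
  counts <- resolve_multimappers(mat, ref$mirna_id, policy)
  mapped <- sum(mat$count)
  oth <- cls[cls$category == "others_isomir", ]
  others_counts <- setNames(numeric(0), character(0))
  if (nrow(oth)) {
    s <- rowsum(oth$count, oth$mirna_id)
    others_counts <- setNames(as.numeric(s), rownames(s))
  }
  structure(
    list(
      counts = counts,
      rpm = if (mapped > 0) compute_rpm(counts, mapped) else counts,
      others_counts = others_counts,
      composition = composition_breakdown(cls, cls$count),
      library_size = mapped,
      n_postclipped = sum(cls$count),
      assignments = cls,
      policy = policy
    ),
    class = "mirsat_quant"
  )
}

#' Assemble a multi-sample count table
#'
#' @param quants Named list of `mirsat_quant` objects (one per sample).
#' @return List of class `mirsat_count_table`: `counts` (matrix miRNA x
#'   sample), `library_sizes` (mapped totals; equal to the column sums under
#'   the uniform and em policies), `others` (matrix of isomiR tallies).
#' @export
count_table <- function(quants) {
  stopifnot(length(quants) >= 1L)
  ids <- names(quants[[1]]$counts)
  counts <- vapply(quants, function(q) q$counts[ids], numeric(length(ids)))
  rownames(counts) <- ids
  oth_ids <- sort(unique(unlist(lapply(quants, function(q) names(q$others_counts)))))
  others <- vapply(quants, function(q) {
    v <- setNames(numeric(length(oth_ids)), oth_ids)
    v[names(q$others_counts)] <- q$others_counts
    v
  }, numeric(length(oth_ids)))
  if (length(oth_ids)) rownames(others) <- oth_ids
  structure(
    list(
      counts = counts,
      library_sizes = vapply(quants, function(q) q$library_size, numeric(1)),
      others = others
    ),
    class = "mirsat_count_table"
  )
}

#' Round a count matrix to integers (half-to-even)
#'
#' Fractional counts arise only from multimapper redistribution; the exact
#' test requires integers, so rounding happens once at this boundary and the
#' number of affected cells is reported.
#'
#' @param counts Numeric matrix.
#' @return Integer-valued matrix.
#' @export
round_counts <- function(counts) {
  out <- round(counts)
  changed <- sum(out != counts)
  if (changed > 0) {
    message(sprintf("round_counts: %d fractional cell(s) rounded half-to-even", changed))
  }
  out
}
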