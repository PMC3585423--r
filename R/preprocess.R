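#' Quality-control summary of a read set
#'
#' Per-cycle mean phred quality, read-length histogram, and a pass flag that
#' is true iff every cycle's mean quality is at least `min_mean` (default
#' Q28, inclusive).
#'
#' @param reads Read set tibble (`read_id`, `sequence`, `quality`).
#' @param min_mean Pass threshold on per-position mean quality.
#' @return List of class `mirsat_qc`: `per_position` (tibble `position`,
#'   `mean_quality`, `n`), `length_histogram` (tibble `length`, `n`),
#'   `pass`, `failing_positions`.
#' @export
qc_summary <- function(reads, min_mean = 28) {
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    stop_mirsat(
      sprintf("sequence/quality length mismatch in record(s): %s",
              paste(head(reads$read_id[bad], 5L), collapse = ", ")),
      "mirsat_malformed_read"
    )
  }
  if (nrow(reads) == 0L) {
    return(structure(
      list(
        per_position = tibble::tibble(position = integer(0), mean_quality = numeric(0), n = integer(0)),
        length_histogram = tibble::tibble(length = integer(0), n = integer(0)),
        pass = TRUE, failing_positions = integer(0)
      ),
      class = "mirsat_qc"
    ))
  }
  lens <- nchar(reads$quality)
  phred <- as.integer(charToRaw(paste(reads$quality, collapse = ""))) - 33L
  pos <- sequence(lens)
  n_at <- tabulate(pos)
  mean_q <- as.numeric(rowsum(phred, pos)) / n_at
  failing <- which(mean_q < min_mean)
  lh <- table(lens)
  structure(
    list(
      per_position = tibble::tibble(
        position = seq_along(mean_q), mean_quality = mean_q, n = n_at
      ),
      length_histogram = tibble::tibble(
        length = as.integer(names(lh)), n = as.integer(lh)
      ),
      pass = length(failing) == 0L,
      failing_positions = failing
    ),
    class = "mirsat_qc"
  )
}

# leftmost position (1-based) at which the adapter seed matches each
# sequence with at most `max_mismatch` mismatches; -1 when absent.
# A terminal partial overlap shorter than the seed never matches.
find_adapter <- function(sequence, seed, max_mismatch = 0L) {
  if (max_mismatch == 0L) {
    return(as.integer(regexpr(seed, sequence, fixed = TRUE)))
  }
  k <- nchar(seed)
  maxlen <- max(nchar(sequence), 0L)
  hit <- rep(-1L, length(sequence))
  seed_ch <- strsplit(seed, "")[[1]]
  for (start in seq_len(max(0L, maxlen - k + 1L))) {
    open <- hit == -1L & nchar(sequence) >= start + k - 1L
    if (!any(open)) break
    mm <- integer(sum(open))
    win <- substr(sequence[open], start, start + k - 1L)
    for (j in seq_len(k)) {
      cj <- substr(win, j, j)
      mm <- mm + (cj != seed_ch[j] | cj == "N") # N never matches the seed
    }
    ok <- mm <= max_mismatch
    hit[which(open)[ok]] <- start
  }
  hit
}

#' Clip the 3' adapter from a single read
#'
#' Clips at the leftmost occurrence of the adapter's first `min_overlap`
#' bases (exact by default). An adapter starting at position 1 makes the
#' read `adapter_only`; no occurrence leaves the read `unclipped` (retained
#' downstream, but flagged). The quality string is truncated in lockstep.
#'
#' @param read One-row read set (or list with `read_id`, `sequence`,
#'   `quality`).
#' @param adapter Adapter sequence (non-empty, `nchar >= min_overlap`).
#' @param min_overlap Seed length used for matching (default 8).
#' @param max_mismatch 0 (exact, default) or 1 mismatch tolerated in the seed.
#' @return List with `status` (`"clipped"`, `"adapter_only"`, `"unclipped"`)
#'   and `read` (the clipped one-row read set; `NULL` for adapter-only).
#' @export
clip_adapter <- function(read, adapter, min_overlap = 8L, max_mismatch = 0L) {
  res <- clip_read_set(read_set(read$read_id, read$sequence, read$quality),
                       adapter, min_overlap, max_mismatch)
  status <- unname(res$status[1])
  list(
    status = status,
    read = if (status == "adapter_only") NULL else res$reads[1, ]
  )
}

#' Clip the 3' adapter from every read of a set
#'
#' Vectorized version of [clip_adapter()]. Adapter-only reads are dropped
#' from the returned set; unclipped reads are retained unchanged and
#' flagged.
#'
#' @inheritParams clip_adapter
#' @param reads Read set tibble.
#' @return List: `reads` (clipped + unclipped retained reads), `status`
#'   (per input read: clipped/adapter_only/unclipped, named by read id),
#'   `n_input`, `n_adapter_only`, `n_unclipped`.
#' @export
clip_read_set <- function(reads, adapter, min_overlap = 8L, max_mismatch = 0L) {
  if (!nzchar(adapter)) stop_mirsat("adapter must be non-empty", "mirsat_bad_adapter")
  if (min_overlap < 1L || nchar(adapter) < min_overlap) {
    stop_mirsat("need adapter length >= min_overlap >= 1", "mirsat_bad_adapter")
  }
  seed <- substr(adapter, 1L, min_overlap)
  pos <- find_adapter(reads$sequence, seed, max_mismatch)
  status <- ifelse(pos == 1L, "adapter_only", ifelse(pos > 1L, "clipped", "unclipped"))
  keep <- status != "adapter_only"
  out <- reads[keep, ]
  p <- pos[keep]
  cl <- p > 1L
  out$sequence[cl] <- substr(out$sequence[cl], 1L, p[cl] - 1L)
  out$quality[cl] <- substr(out$quality[cl], 1L, p[cl] - 1L)
  list(
    reads = out,
    status = setNames(status, reads$read_id),
    n_input = nrow(reads),
    n_adapter_only = sum(status == "adapter_only"),
    n_unclipped = sum(status == "unclipped")
  )
}

#' Filter reads by minimum length
#'
#' @param reads Read set tibble.
#' @param min_len Minimum retained length (default 18 nt).
#' @return List: `reads` (retained), `n_too_short`.
#' @export
filter_length <- function(reads, min_len = 18L) {
  stopifnot(min_len >= 1L)
  keep <- nchar(reads$sequence) >= min_len
  list(reads = reads[keep, ], n_too_short = sum(!keep))
}

#' Collapse reads into unique sequences with multiplicities
#'
#' @param reads Read set tibble or character vector of sequences.
#' @return Tibble of class `mirsat_collapsed` (`sequence`, `count`), ordered
#'   by descending multiplicity then lexicographically; attribute `total`
#'   conserves the input read count.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  out <- dplyr::count(tibble::tibble(sequence = seqs), .data$sequence, name = "count")
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
  attr(out, "total") <- length(seqs)
  class(out) <- c("mirsat_collapsed", class(out))
  out
}

#' Clipping report
#'
#' Accounting of the pre-alignment filter: `n_input = n_adapter_only +
#' n_too_short + n_retained`; unclipped reads are retained and additionally
#' counted in `n_unclipped`.
#'
#' @param n_input,n_adapter_only,n_too_short,n_unclipped,n_retained Counts.
#' @return List of class `mirsat_clip_report`.
#' @export
clip_report <- function(n_input, n_adapter_only, n_too_short, n_unclipped,
                        n_retained) {
  r <- list(
    n_input = n_input, n_adapter_only = n_adapter_only,
    n_too_short = n_too_short, n_unclipped = n_unclipped,
    n_retained = n_retained
  )
  if (n_input != n_adapter_only + n_too_short + n_retained) {
    stop_mirsat("clip report counts are inconsistent", "mirsat_bad_report")
  }
  structure(r, class = "mirsat_clip_report")
}

#' @param report A clip report.
#' @param path JSON output path.
#' @rdname clip_report
#' @export
write_clip_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full pre-alignment filter on a read set
#'
#' Adapter clipping, adapter-only removal, minimum-length filtering and read
#' collapsing, with full read accounting.
#'
#' @inheritParams clip_read_set
#' @param min_len Minimum post-clip length (default 18 nt).
#' @return List of class `mirsat_preprocessed`: `reads` (retained clipped
#'   read set), `collapsed` (collapsed read set), `report`
#'   (`mirsat_clip_report`), `status` (per input read id:
#'   clipped/adapter_only/unclipped/too_short).
#' @export
preprocess_reads <- function(reads, adapter = ILLUMINA_3P_ADAPTER,
                             min_len = 18L, min_overlap = 8L,
                             max_mismatch = 0L) {
  cl <- clip_read_set(reads, adapter, min_overlap, max_mismatch)
  fl <- filter_length(cl$reads, min_len)
  status <- cl$status
  short_ids <- setdiff(cl$reads$read_id, fl$reads$read_id)
  status[short_ids] <- "too_short"
  rep <- clip_report(
    n_input = cl$n_input,
    n_adapter_only = cl$n_adapter_only,
    n_too_short = fl$n_too_short,
    n_unclipped = sum(status == "unclipped"),
    n_retained = nrow(fl$reads)
  )
  structure(
    list(
      reads = fl$reads,
      collapsed = collapse_reads(fl$reads),
      report = rep,
      status = status
    ),
    class = "mirsat_preprocessed"
  )
}
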