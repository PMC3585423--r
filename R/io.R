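#' Construct a read set
#'
#' A read set is the in-memory form of a FASTQ file: a tibble with columns
#' `read_id`, `sequence` and `quality` (phred+33 encoded, same width as the
#' sequence).
#'
#' @param read_id Character vector of identifiers.
#' @param sequence Character vector over `{A,C,G,T,N}`.
#' @param quality Character vector of phred+33 quality strings.
#' @return A tibble of class `mirsat_read_set`.
#' @export
read_set <- function(read_id, sequence, quality) {
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad)) {
    stop_mirsat(
      sprintf(
        "sequence/quality length mismatch in record(s): %s",
        paste(head(read_id[bad], 5L), collapse = ", ")
      ),
      "mirsat_malformed_read"
    )
  }
  out <- tibble::tibble(
    read_id = as.character(read_id),
    sequence = as.character(sequence),
    quality = as.character(quality)
  )
  class(out) <- c("mirsat_read_set", class(out))
  out
}

#' Read and write FASTQ files (phred+33)
#'
#' Thin wrappers over Biostrings' quality-scaled string sets.
#'
#' @param path File path.
#' @return `read_fastq()` returns a read set tibble.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns while dropping (empty) mcols
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  read_set(
    read_id = names(x) %||% as.character(seq_along(x)),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}

#' @param reads A read set tibble.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  # Biostrings warns that (empty) metadata columns are dropped along the way
  withCallingHandlers(
    {
      dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
      qs <- Biostrings::QualityScaledDNAStringSet(
        dna, Biostrings::PhredQuality(reads$quality)
      )
      Biostrings::writeQualityScaledXStringSet(qs, path)
    },
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  invisible(path)
}

#' Read and write reference FASTA
#'
#' References are written wrapped at 70 columns in the DNA alphabet; on
#' reading, any `U`/`u` (RNA-alphabet deposits) is normalized to `T`.
#'
#' @param path File path.
#' @return `read_reference_fasta()` returns a mature reference tibble
#'   (`mirna_id`, `sequence`).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("Uu", "Tt", as.character(x)))
  mature_reference(tibble::tibble(mirna_id = names(x), sequence = unname(seqs)))
}

#' @param ref A mature reference tibble.
#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$mirna_id))
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' Write a collapsed read set as multiplicity-annotated FASTA
#'
#' Uses the `>seqNNN_xMULT` header dialect consumed by miRDeep2-style
#' mappers.
#'
#' @param collapsed A collapsed read set (`sequence`, `count`).
#' @param path File path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  dna <- Biostrings::DNAStringSet(setNames(collapsed$sequence, ids))
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' Read or write a per-read truth ledger as TSV
#'
#' @param ledger Ledger tibble (`read_id`, `category`, `source_id`, `edits`,
#'   `insert`).
#' @param path File path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  tibble::as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE,
    colClasses = "character", na.strings = "NA"
  ))
}

#' Write a count table as TSV (rows miRNA, columns samples)
#'
#' @param counts Numeric matrix, rownames miRNA ids.
#' @param path File path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
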