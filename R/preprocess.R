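#' Trim the 3' adapter from a single read
#'
#' The adapter is located by an exact match of its first
#' `min_adapter_match` nucleotides; the leftmost occurrence wins and the
#' read is cut immediately before it. Reads are kept only when adapter
#' evidence is present, the trimmed insert is at least `min_trimmed_len`
#' nt, and the insert contains no ambiguous character (anything outside
#' A/C/G/T). Rejection is a categorized outcome, never an error.
#'
#' @param read_sequence Read sequence (character scalar).
#' @param adapter_sequence Adapter sequence; must be at least
#'   `min_adapter_match` nt.
#' @param min_adapter_match Minimum adapter evidence (nt), default 6.
#' @param min_trimmed_len Minimum kept insert length (nt), default 15.
#' @return A list with `kept` (logical), `sequence` (trimmed insert or
#'   `NA`), and `reject_reason` (one of `"none"`, `"no_adapter"`,
#'   `"too_short"`, `"ambiguous_base"`).
#' @export
trim_adapter <- function(read_sequence, adapter_sequence,
                         min_adapter_match = 6L, min_trimmed_len = 15L) {
  stopifnot(length(read_sequence) == 1L, nzchar(read_sequence),
            nchar(adapter_sequence) >= min_adapter_match)
  res <- trim_reads(data.frame(read_id = "r", sequence = read_sequence,
                               stringsAsFactors = FALSE),
                    adapter_sequence, min_adapter_match, min_trimmed_len)
  list(kept = res$kept, sequence = if (res$kept) res$sequence else NA_character_,
       reject_reason = res$reject_reason)
}

#' Trim and filter a read set
#'
#' Vectorized form of [trim_adapter()] over a read-set data.frame.
#'
#' @param reads Data.frame with `read_id` and `sequence` columns
#'   (as returned by [read_fastq()]).
#' @param adapter_sequence 3' adapter sequence.
#' @param min_adapter_match,min_trimmed_len See [trim_adapter()].
#' @return The read set with `sequence` replaced by the trimmed insert for
#'   kept reads (rejected reads keep their original sequence), plus updated
#'   `kept` and `reject_reason` columns.
#' @export
trim_reads <- function(reads, adapter_sequence, min_adapter_match = 6L,
                       min_trimmed_len = 15L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (nchar(adapter_sequence) < min_adapter_match)
    stop("adapter shorter than min_adapter_match", call. = FALSE)
  seed <- toupper(substr(adapter_sequence, 1L, min_adapter_match))
  seqs <- toupper(reads$sequence)
  pos <- regexpr(seed, seqs, fixed = TRUE)  # leftmost occurrence
  has_adapter <- pos > 0L
  insert <- ifelse(has_adapter, substr(seqs, 1L, pos - 1L), seqs)
  long_enough <- nchar(insert) >= min_trimmed_len
  clean <- !grepl("[^ACGT]", insert)
  reason <- rep("none", nrow(reads))
  reason[!clean] <- "ambiguous_base"
  reason[clean & !long_enough] <- "too_short"
  reason[!has_adapter] <- "no_adapter"
  kept <- has_adapter & long_enough & clean
  out <- reads
  out$sequence <- ifelse(kept, insert, reads$sequence)
  out$kept <- kept
  out$reject_reason <- reason
  out
}

#' Trimming report
#'
#' @param trimmed Output of [trim_reads()].
#' @return One-row-per-reason data.frame of read counts plus the kept total.
#' @export
trimming_report <- function(trimmed) {
  tab <- table(factor(trimmed$reject_reason,
                      levels = c("none", "no_adapter", "too_short",
                                 "ambiguous_base")))
  data.frame(reason = names(tab), reads = as.integer(tab),
             stringsAsFactors = FALSE)
}
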