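#' Read a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; record ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              format = "fasta")
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Records are strict 4-line blocks. Qualities are parsed but ignored
#' downstream: every filtering rule in the pipeline is sequence-only.
#' Sequences are retained verbatim (including non-ACGT characters, which
#' the trimmer later rejects).
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `read_id`, `sequence`, `kept`
#'   (all `TRUE`) and `reject_reason` (all `"none"`).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4L + 1L, " in ", path, call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      kept = logical(), reject_reason = character(),
                      stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad))
    stop("malformed FASTQ record at record index ", bad[1], " in ", path,
         call. = FALSE)
  data.frame(
    read_id = sub("\\s.*$", "", sub("^@", "", hdr)),
    sequence = toupper(seq),
    kept = TRUE,
    reject_reason = "none",
    stringsAsFactors = FALSE
  )
}

#' Write a read set to a FASTQ file
#'
#' Constant placeholder qualities ("I") are emitted; the pipeline never
#' consumes quality values.
#'
#' @param reads A data.frame with `read_id` and `sequence` columns.
#' @param path Output path.
#' @param keep_only Write only rows with `kept == TRUE` (if the column
#'   exists). Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, keep_only = TRUE) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (keep_only && "kept" %in% names(reads)) reads <- reads[reads$kept, ]
  qual <- strrep("I", nchar(reads$sequence))
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                         "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a mature-miRNA annotation table
#'
#' TSV with columns `hairpin_id`, `mature_id`, `start`, `end`
#' (1-based inclusive coordinates on the hairpin, miRBase convention).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with those four columns.
#' @export
read_mature_annotations <- function(path) {
  if (!file.exists(path))
    stop("mature annotation file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("hairpin_id", "mature_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop("mature annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab[need]
}

#' Write a mature-miRNA annotation table
#' @param matures Data.frame with `hairpin_id`, `mature_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_annotations <- function(matures, path) {
  utils::write.table(matures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV
#'
#' Rows are mature miRNA ids, columns are samples. An optional leading
#' comment line `# groups: <tab-separated labels>` carries the per-sample
#' group labels, restored as the `"groups"` attribute.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with a `"groups"` attribute (character or NULL).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  groups <- NULL
  skip <- 0L
  if (startsWith(first, "# groups:")) {
    groups <- strsplit(trimws(sub("^# groups:", "", first)), "\t")[[1]]
    skip <- 1L
  }
  tab <- utils::read.delim(path, skip = skip, row.names = 1L,
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  if (!is.null(groups)) {
    if (length(groups) != ncol(m))
      stop("group label count does not match sample count in ", path,
           call. = FALSE)
    attr(m, "groups") <- groups
  }
  m
}

#' Write a count (or normalized) matrix TSV
#' @param counts Numeric matrix with row and column names.
#' @param path Output path.
#' @param groups Optional per-sample group labels written as a
#'   `# groups:` comment line.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, groups = attr(counts, "groups")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(groups))
    writeLines(paste0("# groups:\t", paste(groups, collapse = "\t")), con)
  writeLines(paste(c("mirna", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with samples in rows and assays in columns; the first column holds
#' sample ids and a `group` column holds group labels. Empty cells or the
#' strings `ND`/`NA` denote non-detection.
#'
#' @param path Path to the CSV file.
#' @param reference_assay Reference assay column name (default `"U6"`).
#' @param calibrator_sample Sample id of the single calibrator; defaults to
#'   the first sample.
#' @return A `ct_table` object (see [ct_table()]).
#' @export
read_ct_table <- function(path, reference_assay = "U6",
                          calibrator_sample = NULL) {
  if (!file.exists(path)) stop("Ct table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_ids <- tab[[1]]
  if (!"group" %in% names(tab))
    stop("Ct table must contain a 'group' column", call. = FALSE)
  groups <- tab$group
  assay_cols <- setdiff(names(tab), c(names(tab)[1], "group"))
  ct <- as.matrix(tab[assay_cols])
  ct[ct %in% c("ND", "NA", "")] <- NA
  ct <- matrix(as.numeric(ct), nrow = nrow(tab),
               dimnames = list(sample_ids, assay_cols))
  if (is.null(calibrator_sample)) calibrator_sample <- sample_ids[1]
  ct_table(ct, groups = stats::setNames(groups, sample_ids),
           reference_assay = reference_assay,
           calibrator_sample = calibrator_sample)
}

#' Write a qPCR Ct table CSV
#' @param x A `ct_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  out <- data.frame(sample = rownames(x$ct),
                    group = unname(x$groups[rownames(x$ct)]),
                    as.data.frame(x$ct, check.names = FALSE),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "ND")
  invisible(path)
}

#' Read a long-format target-prediction score table
#'
#' TSV with columns `program`, `mirna`, `gene`, `score`.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with those columns.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("program", "mirna", "gene", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab[need]
}

#' Read a pathway gene-set file
#'
#' TSV with columns `pathway` and `gene`, one gene per line.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors (genes per pathway).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% names(tab)))
    stop("gene set file must have columns pathway, gene", call. = FALSE)
  split(tab$gene, tab$pathway)
}

# Generic TSV writer used for stage outputs (DE tables, reports).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
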