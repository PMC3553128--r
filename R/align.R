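# Hamming alignment of full-length reads against small reference sets.
#
# Encoding: A/C/G/T -> 1..4. 'N' (or any other character) in a READ gets
# code -1 and in a REFERENCE code -2, so an ambiguous base mismatches
# everything, including another ambiguous base.

.encode_seq <- function(s, is_read) {
  v <- utf8ToInt(s)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out[out == 0L] <- if (is_read) -1L else -2L
  out
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Mismatch counts of a length-L read at every offset of one reference.
# ref_int: encoded reference; read_int: encoded read. Returns integer
# vector of length max(0, M - L + 1).
.hamming_profile <- function(read_int, ref_int) {
  L <- length(read_int)
  M <- length(ref_int)
  if (L > M) return(integer(0))
  K <- M - L + 1L
  win <- ref_int[outer(seq_len(L), 0:(K - 1L), "+")]
  dim(win) <- c(L, K)
  colSums(win != read_int)
}

#' All ungapped full-length placements of a read within mismatch budget
#'
#' Scans every offset of every reference sequence and reports placements
#' where the entire read fits consecutively with Hamming distance at most
#' `max_mm`. An `N` in the read mismatches every reference base (including
#' reference `N`). Reads longer than every reference yield an empty result.
#'
#' @param read Read sequence (character scalar).
#' @param reference_db Named character vector of reference sequences.
#' @param max_mm Maximum number of mismatches.
#' @return Data.frame with columns `target_id`, `start` (0-based offset)
#'   and `mismatches`, sorted by (mismatches, target_id, start).
#' @export
align_hamming <- function(read, reference_db, max_mm) {
  stopifnot(length(read) == 1L, is.character(reference_db),
            length(reference_db) >= 1L, !is.null(names(reference_db)))
  read_int <- .encode_seq(toupper(read), is_read = TRUE)
  hits <- lapply(names(reference_db), function(id) {
    prof <- .hamming_profile(read_int,
                             .encode_seq(toupper(reference_db[[id]]),
                                         is_read = FALSE))
    ok <- which(prof <= max_mm)
    if (!length(ok)) return(NULL)
    data.frame(target_id = id, start = ok - 1L, mismatches = prof[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(target_id = character(), start = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  out[order(out$mismatches, out$target_id, out$start), , drop = FALSE]
}

# Best (minimum) mismatch count of each unique sequence against a
# reference set, bounded by max_mm; returns for each sequence the best
# mismatch count (NA when no placement <= max_mm) and, optionally, every
# best-tier hairpin placement for mature assignment.
#
# Windows are cached per (reference, read length) in `cache`, an
# environment, so batches of reads share the shifted-window matrices.
.batch_best_hits <- function(seqs, reference_db, max_mm, cache = NULL,
                             keep_hits = FALSE) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ref_int <- lapply(reference_db, function(s)
    .encode_seq(toupper(s), is_read = FALSE))
  best <- rep(NA_integer_, length(seqs))
  hits <- if (keep_hits) vector("list", length(seqs)) else NULL
  lens <- nchar(seqs)
  for (i in seq_along(seqs)) {
    read_int <- .encode_seq(seqs[[i]], is_read = TRUE)
    L <- lens[i]
    bi <- NA_integer_
    rows <- list()
    for (id in names(ref_int)) {
      key <- paste0(id, ":", L)
      win <- cache[[key]]
      if (is.null(win)) {
        ri <- ref_int[[id]]
        M <- length(ri)
        if (L > M) { cache[[key]] <- integer(0); next }
        K <- M - L + 1L
        win <- ri[outer(seq_len(L), 0:(K - 1L), "+")]
        dim(win) <- c(L, K)
        cache[[key]] <- win
      }
      if (!length(win)) next
      prof <- colSums(win != read_int)
      m <- min(prof)
      if (m <= max_mm && (is.na(bi) || m <= bi)) {
        bi <- if (is.na(bi)) m else min(bi, m)
        if (keep_hits)
          rows[[id]] <- data.frame(target_id = id, start = which(prof == m) - 1L,
                                   mismatches = m, stringsAsFactors = FALSE)
      }
    }
    best[i] <- bi
    if (keep_hits && !is.na(bi)) {
      tab <- do.call(rbind, rows)
      hits[[i]] <- tab[tab$mismatches == bi, , drop = FALSE]
    }
  }
  list(best = best, hits = hits)
}

#' Assign a hairpin placement to a mature miRNA
#'
#' A read counts toward a mature arm when its placement interval on the
#' hairpin overlaps that arm by at least `min_overlap` nt. If two distinct
#' matures on the hairpin both reach the overlap threshold (e.g. a
#' loop-spanning read) the assignment is ambiguous and the read is not
#' counted.
#'
#' @param alignment One row of [align_hamming()] output against a hairpin
#'   (list or data.frame row with `target_id`, `start`), plus the read
#'   length via `read_length`.
#' @param reference A `hairpin_reference`.
#' @param read_length Length of the aligned read (nt).
#' @param min_overlap Minimum read/mature overlap (nt), default 7.
#' @return The mature id (character), `NA_character_` if no mature reaches
#'   the threshold, or `"ambiguous"` if two or more do.
#' @export
assign_to_mature <- function(alignment, reference, read_length,
                             min_overlap = 7L) {
  stopifnot(inherits(reference, "hairpin_reference"))
  mat <- reference$matures[reference$matures$hairpin_id == alignment$target_id,
                           , drop = FALSE]
  if (!nrow(mat)) return(NA_character_)
  # read interval, 0-based half-open: [start, start + L)
  r0 <- alignment$start
  r1 <- alignment$start + read_length
  m0 <- mat$start - 1L
  m1 <- mat$end
  overlap <- pmin(r1, m1) - pmax(r0, m0)
  hit <- mat$mature_id[overlap >= min_overlap]
  if (length(hit) == 0L) return(NA_character_)
  if (length(hit) >= 2L) return("ambiguous")
  hit
}

#' Categorize reads through the sequential mapping cascade
#'
#' Tier 1 maps each read against the miRNA hairpins with at most
#' `max_mm_primary` mismatches; hits are assigned to a mature arm (unique
#' mature with >= `min_mature_overlap` nt overlap -> `mirna_mm01`;
#' multiple matures at the best mismatch tier -> `ambiguous_mature`; no
#' mature reached -> the read falls through). Unmatched reads then cascade
#' through the non-miRNA ncRNA, genome and contaminant databases at up to
#' `max_mm_decoy` mismatches, are finally retried on the hairpins with
#' mismatches in the `relaxed_mm` window (`mirna_mm23_excluded`, never
#' counted), and otherwise end `unmapped`.
#'
#' Multi-hairpin hits at the best mismatch count that all imply the same
#' mature id (paralogous precursors) count once for that mature; distinct
#' implied matures are discarded as ambiguous.
#'
#' @param reads Data.frame with `read_id`, `sequence` (trimmed, kept reads).
#' @param reference A `hairpin_reference`.
#' @param decoys Named list with character-vector elements `ncrna`,
#'   `genome`, `contaminant` (any may be omitted or empty).
#' @param config A [pipeline_config()].
#' @return Data.frame with `read_id`, `sequence`, `category` and
#'   `mature_id` (`NA` except for `mirna_mm01` reads).
#' @export
categorize_reads <- function(reads, reference, decoys = list(),
                             config = pipeline_config()) {
  stopifnot(is.data.frame(reads), inherits(reference, "hairpin_reference"))
  validate_config(config)
  seqs <- toupper(reads$sequence)
  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  n <- length(uniq)
  category <- rep(NA_character_, n)
  mature <- rep(NA_character_, n)
  caches <- new.env(parent = emptyenv())
  cache_for <- function(tag) {
    if (is.null(caches[[tag]])) caches[[tag]] <- new.env(parent = emptyenv())
    caches[[tag]]
  }
  # stranded library by default; the revcomp flag additionally matches the
  # reverse complement of each read (forward wins at equal mismatches)
  uniq_rc <- if (config$revcomp) vapply(uniq, .revcomp, "") else NULL

  .best2 <- function(which_idx, db, max_mm, tag, keep_hits = FALSE) {
    cache <- cache_for(tag)
    f <- .batch_best_hits(uniq[which_idx], db, max_mm, cache = cache,
                          keep_hits = keep_hits)
    if (is.null(uniq_rc)) return(f)
    r <- .batch_best_hits(uniq_rc[which_idx], db, max_mm, cache = cache,
                          keep_hits = keep_hits)
    take_r <- !is.na(r$best) & (is.na(f$best) | r$best < f$best)
    f$best[take_r] <- r$best[take_r]
    if (keep_hits) f$hits[take_r] <- r$hits[take_r]
    f
  }

  # Tier 1: hairpins at <= max_mm_primary, with mature assignment
  t1 <- .best2(seq_len(n), reference$hairpins, config$max_mm_primary,
               tag = "hairpin", keep_hits = TRUE)
  for (i in seq_len(n)) {
    if (is.na(t1$best[i])) next
    hits <- t1$hits[[i]]
    L <- nchar(uniq[i])
    assigned <- character(0)
    ambiguous <- FALSE
    for (k in seq_len(nrow(hits))) {
      a <- assign_to_mature(hits[k, ], reference, L,
                            config$min_mature_overlap)
      if (is.na(a)) next
      if (a == "ambiguous") { ambiguous <- TRUE; break }
      assigned <- c(assigned, a)
    }
    assigned <- unique(assigned)
    if (ambiguous || length(assigned) > 1L) {
      category[i] <- "ambiguous_mature"
    } else if (length(assigned) == 1L) {
      category[i] <- "mirna_mm01"
      mature[i] <- assigned
    }
    # no mature reached: condition (b) fails; read falls through the cascade
  }

  todo <- which(is.na(category))
  tiers <- list(ncrna = decoys$ncrna, genome = decoys$genome,
                contaminant = decoys$contaminant)
  for (tier in names(tiers)) {
    db <- tiers[[tier]]
    if (is.null(db) || !length(db) || !length(todo)) next
    bb <- .best2(todo, db, config$max_mm_decoy, tag = tier)
    hit <- !is.na(bb$best)
    category[todo[hit]] <- tier
    todo <- todo[!hit]
  }

  if (length(todo)) {
    # relaxed hairpin remap: mismatches within the relaxed window only
    bb <- .best2(todo, reference$hairpins, config$relaxed_mm[2],
                 tag = "hairpin")
    hit <- !is.na(bb$best) & bb$best >= config$relaxed_mm[1] &
      bb$best <= config$relaxed_mm[2]
    category[todo[hit]] <- "mirna_mm23_excluded"
    todo <- todo[!hit]
  }
  category[is.na(category)] <- "unmapped"

  data.frame(read_id = reads$read_id, sequence = reads$sequence,
             category = category[idx], mature_id = mature[idx],
             stringsAsFactors = FALSE)
}

#' Build the raw count matrix from categorized reads
#'
#' Only unambiguous tier-1 mature assignments (`mirna_mm01`) contribute.
#' Every mature listed in the reference appears as a row, so matures with
#' no reads anywhere are kept as all-zero rows.
#'
#' @param categorized Output of [categorize_reads()] with an additional
#'   `sample_id` column.
#' @param sample_ids Character vector giving the column order; every
#'   `sample_id` in `categorized` must appear here.
#' @param reference A `hairpin_reference` supplying the row universe.
#' @param groups Optional per-sample group labels (same length/order as
#'   `sample_ids`), attached as the `"groups"` attribute.
#' @return Integer matrix, matures x samples.
#' @export
build_count_matrix <- function(categorized, sample_ids, reference,
                               groups = NULL) {
  stopifnot("sample_id" %in% names(categorized),
            inherits(reference, "hairpin_reference"))
  unknown <- setdiff(unique(categorized$sample_id), sample_ids)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rows <- reference$matures$mature_id
  keep <- categorized[categorized$category == "mirna_mm01", , drop = FALSE]
  m <- table(factor(keep$mature_id, levels = rows),
             factor(keep$sample_id, levels = sample_ids))
  m <- matrix(as.integer(m), nrow = length(rows),
              dimnames = list(rows, sample_ids))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(sample_ids))
    attr(m, "groups") <- as.character(groups)
  }
  m
}

#' Per-category read summary
#'
#' Mirrors the flow-chart accounting of the sequential cascade: reads per
#' category and the percentage of all kept reads.
#'
#' @param categorized Output of [categorize_reads()].
#' @return Data.frame with `category`, `reads`, `pct`.
#' @export
category_summary <- function(categorized) {
  lev <- c("mirna_mm01", "ambiguous_mature", "ncrna", "genome",
           "contaminant", "mirna_mm23_excluded", "unmapped")
  tab <- table(factor(categorized$category, levels = lev))
  data.frame(category = lev, reads = as.integer(tab),
             pct = round(100 * as.integer(tab) / max(1L, nrow(categorized)), 3),
             stringsAsFactors = FALSE)
}
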