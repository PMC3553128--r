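#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline. The defaults are the
#' values used throughout the original study design: one mismatch for the
#' primary hairpin pass, up to three for the decoy passes, a 2-3 mismatch
#' window for the relaxed hairpin remap, a minimum 7-nt overlap with a
#' mature arm, a minimum trimmed read length of 15 nt, a minimum 6-nt
#' adapter match, a 25-read low-count threshold for the validation filter,
#' 5\% FDR, and the top-5\%/at-least-2-programs (top-1\% fallback) consensus
#' target rule.
#'
#' @param max_mm_primary Maximum mismatches for the primary hairpin pass.
#' @param max_mm_decoy Maximum mismatches for the decoy passes
#'   (non-miRNA ncRNA, genome, contaminant).
#' @param relaxed_mm Integer vector of length 2: the inclusive mismatch
#'   window for the relaxed hairpin remap of still-unmapped reads.
#' @param min_mature_overlap Minimum overlap (nt) between a read placement
#'   and a mature arm for the read to count toward that mature miRNA.
#' @param min_trimmed_len Minimum trimmed read length (nt) to keep a read.
#' @param min_adapter_match Minimum number of adapter nucleotides that must
#'   be found in a read for it to be included.
#' @param low_count_threshold Reads per group below which a differentially
#'   expressed miRNA is flagged as low-count (excluded from validation).
#' @param fdr_q FDR level for Benjamini-Hochberg significance calls.
#' @param top_pct_shared Per-program score percentile for shared consensus
#'   targets.
#' @param top_pct_fallback Per-program score percentile for the
#'   single-program fallback rule.
#' @param min_programs Minimum number of programs that must rank a gene in
#'   the top `top_pct_shared` for it to be a shared target.
#' @param revcomp Also match the reverse complement of each read
#'   (off by default: stranded small-RNA libraries).
#' @param minus_rt_margin Cycles; a qPCR assay whose minus-RT control
#'   amplifies within this many cycles of its test wells is flagged invalid.
#' @param ct_ceiling Ct value assigned to non-detected assays when ranking
#'   for the tissue/cell-line correlation.
#' @param seed Integer seed for any randomized stage.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(max_mm_primary = 1L,
                            max_mm_decoy = 3L,
                            relaxed_mm = c(2L, 3L),
                            min_mature_overlap = 7L,
                            min_trimmed_len = 15L,
                            min_adapter_match = 6L,
                            low_count_threshold = 25L,
                            fdr_q = 0.05,
                            top_pct_shared = 0.05,
                            top_pct_fallback = 0.01,
                            min_programs = 2L,
                            revcomp = FALSE,
                            minus_rt_margin = 5,
                            ct_ceiling = 40,
                            seed = 1L) {
  cfg <- list(
    max_mm_primary = as.integer(max_mm_primary),
    max_mm_decoy = as.integer(max_mm_decoy),
    relaxed_mm = as.integer(relaxed_mm),
    min_mature_overlap = as.integer(min_mature_overlap),
    min_trimmed_len = as.integer(min_trimmed_len),
    min_adapter_match = as.integer(min_adapter_match),
    low_count_threshold = as.integer(low_count_threshold),
    fdr_q = as.numeric(fdr_q),
    top_pct_shared = as.numeric(top_pct_shared),
    top_pct_fallback = as.numeric(top_pct_fallback),
    min_programs = as.integer(min_programs),
    revcomp = isTRUE(revcomp),
    minus_rt_margin = as.numeric(minus_rt_margin),
    ct_ceiling = as.numeric(ct_ceiling),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config` list.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config") || is.list(cfg))
  chk_pos_int <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      stop("config: '", name, "' must be a positive integer", call. = FALSE)
  }
  for (nm in c("max_mm_decoy", "min_mature_overlap", "min_trimmed_len",
               "min_adapter_match", "low_count_threshold", "min_programs"))
    chk_pos_int(cfg[[nm]], nm)
  if (cfg$max_mm_primary < 0L)
    stop("config: 'max_mm_primary' must be non-negative", call. = FALSE)
  if (length(cfg$relaxed_mm) != 2L || any(cfg$relaxed_mm < 0L) ||
      cfg$relaxed_mm[1] > cfg$relaxed_mm[2])
    stop("config: 'relaxed_mm' must be an ordered pair of mismatch counts",
         call. = FALSE)
  for (nm in c("fdr_q", "top_pct_shared", "top_pct_fallback")) {
    x <- cfg[[nm]]
    if (length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop("config: '", nm, "' must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected. Values override the defaults of [pipeline_config()].
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("config: every non-comment line must be 'key = value'", call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  defaults <- formals(pipeline_config)
  bad <- setdiff(keys, names(defaults))
  if (length(bad))
    stop("config: unknown key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- lapply(seq_along(keys), function(i) {
    k <- keys[i]; v <- vals[i]
    if (k == "revcomp") return(toupper(v) %in% c("TRUE", "T", "1", "YES"))
    if (k == "relaxed_mm") return(as.integer(strsplit(v, "[,; ]+")[[1]]))
    as.numeric(v)
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}
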