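#' Run the full analysis pipeline
#'
#' Chains every stage: adapter trimming, the sequential mapping cascade
#' with mature counting, median-of-ratios normalization,
#' negative-binomial differential expression with BH control and the
#' low-count validation filter, then (when the corresponding inputs are
#' supplied) delta-delta-Ct qPCR analysis with direction concordance and
#' consensus target / pathway analysis. Every emitted table round-trips
#' through its reader in this package.
#'
#' @param paths Named list of input paths: `hairpin_fasta`, `mature_tsv`,
#'   `fastq` (named character vector, one FASTQ per sample),
#'   `groups_tsv` (columns `sample`, `group`); optional `ncrna_fasta`,
#'   `genome_fasta`, `contaminant_fasta`, `ct_csv`, `scores_tsv`,
#'   `gene_sets_tsv`.
#' @param adapter 3' adapter sequence used for trimming.
#' @param out_dir Directory the stage outputs are written to.
#' @param config A [pipeline_config()].
#' @return Invisible list with every stage result: `trimmed` (per-sample),
#'   `trim_report`, `categories`, `category_summary`, `counts`,
#'   `size_factors`, `normalized`, `de`, and when inputs allow, `qpcr`,
#'   `concordance`, `targets`, `shared_graph`, `enrichment`.
#' @export
run_pipeline <- function(paths, adapter, out_dir,
                         config = pipeline_config()) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  need <- c("hairpin_fasta", "mature_tsv", "fastq", "groups_tsv")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("pipeline stage 'inputs' failed: missing path(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (p in c(paths$hairpin_fasta, paths$mature_tsv, paths$groups_tsv,
              paths$fastq))
    if (!file.exists(p))
      stop("pipeline stage 'inputs' failed: file not found: ", p,
           call. = FALSE)

  ref <- stage("reference",
               read_hairpin_reference(paths$hairpin_fasta, paths$mature_tsv))
  grp_tab <- stage("groups", {
    g <- utils::read.delim(paths$groups_tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "group") %in% names(g)))
    g
  })
  samples <- grp_tab$sample
  if (!setequal(samples, names(paths$fastq)))
    stop("pipeline stage 'inputs' failed: FASTQ paths must cover exactly ",
         "the samples in the group table", call. = FALSE)

  decoys <- stage("decoys", list(
    ncrna = if (!is.null(paths$ncrna_fasta)) read_fasta(paths$ncrna_fasta),
    genome = if (!is.null(paths$genome_fasta)) read_fasta(paths$genome_fasta),
    contaminant = if (!is.null(paths$contaminant_fasta))
      read_fasta(paths$contaminant_fasta)))

  trimmed <- list(); categorized <- list()
  for (smp in samples) {
    raw <- stage("read_fastq", read_fastq(paths$fastq[[smp]]))
    tr <- stage("trim", trim_reads(raw, adapter,
                                   config$min_adapter_match,
                                   config$min_trimmed_len))
    trimmed[[smp]] <- tr
    kept <- tr[tr$kept, , drop = FALSE]
    cat_s <- stage("cascade", categorize_reads(kept, ref, decoys, config))
    cat_s$sample_id <- smp
    categorized[[smp]] <- cat_s
  }
  categories <- do.call(rbind, categorized)
  rownames(categories) <- NULL
  trim_report <- do.call(rbind, lapply(samples, function(smp) {
    r <- trimming_report(trimmed[[smp]]); r$sample <- smp; r
  }))
  counts <- stage("count_matrix",
                  build_count_matrix(categories, samples, ref,
                                     groups = grp_tab$group))
  s <- stage("normalize", size_factors(counts))
  norm <- normalize_counts(counts, s)
  de <- stage("differential_expression", {
    alpha <- estimate_dispersion(norm, grp_tab$group)
    nb_exact_test(counts, s, alpha, grp_tab$group, fdr_q = config$fdr_q,
                  low_count_threshold = config$low_count_threshold)
  })

  res <- list(trimmed = trimmed, trim_report = trim_report,
              categories = categories,
              category_summary = category_summary(categories),
              counts = counts, size_factors = s, normalized = norm, de = de)

  if (!is.null(paths$ct_csv)) {
    res$qpcr <- stage("qpcr", {
      ct <- read_ct_table(paths$ct_csv)
      rel <- ddct(ct, minus_rt_margin = config$minus_rt_margin)
      qpcr_group_test(rel, fdr_q = config$fdr_q)
    })
    res$concordance <- stage("concordance",
                             direction_concordance(de, res$qpcr))
  }
  if (!is.null(paths$scores_tsv)) {
    res$targets <- stage("targets", consensus_targets(
      read_score_table(paths$scores_tsv),
      top_pct_shared = config$top_pct_shared,
      top_pct_fallback = config$top_pct_fallback,
      min_programs = config$min_programs))
    res$shared_graph <- stage("shared_targets",
                              shared_target_graph(res$targets, de))
    if (!is.null(paths$gene_sets_tsv)) {
      res$enrichment <- stage("pathways", {
        scores <- read_score_table(paths$scores_tsv)
        pathway_enrichment(unique(res$targets$gene),
                           read_gene_sets(paths$gene_sets_tsv),
                           universe = unique(scores$gene))
      })
    }
  }

  stage("write_outputs", {
    write_tsv(trim_report, file.path(out_dir, "trim_report.tsv"))
    write_tsv(categories[c("read_id", "sample_id", "category", "mature_id")],
              file.path(out_dir, "read_categories.tsv"))
    write_tsv(res$category_summary,
              file.path(out_dir, "category_summary.tsv"))
    write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_count_matrix(norm, file.path(out_dir, "normalized.tsv"))
    write_tsv(data.frame(sample = names(s), size_factor = unname(s)),
              file.path(out_dir, "size_factors.tsv"))
    write_tsv(de, file.path(out_dir, "de_table.tsv"))
    if (!is.null(res$qpcr))
      write_tsv(res$qpcr, file.path(out_dir, "qpcr_table.tsv"))
    if (!is.null(res$concordance))
      write_tsv(res$concordance$table,
                file.path(out_dir, "concordance_report.tsv"))
    if (!is.null(res$targets))
      write_tsv(res$targets, file.path(out_dir, "targets.tsv"))
    if (!is.null(res$enrichment))
      write_tsv(res$enrichment, file.path(out_dir, "pathway_enrichment.tsv"))
  })
  invisible(res)
}
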