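#' Consensus miRNA target selection across prediction programs
#'
#' For each (program, miRNA) the program's predicted genes are ranked
#' best-first and the top `ceil(top_pct_shared * N)` kept (N = genes that
#' program scores for that miRNA). A gene kept by at least `min_programs`
#' programs is a shared target of the miRNA. A miRNA with no shared gene
#' falls back to genes ranked within the top `ceil(top_pct_fallback * N)`
#' by any single program. Rank ties are broken by score then gene id, so
#' the selection is deterministic and invariant under strictly monotone
#' transforms of any program's scores.
#'
#' @param scores Data.frame with columns `program`, `mirna`, `gene`,
#'   `score`; (program, mirna, gene) must be unique.
#' @param higher_is_better Named logical vector declaring each program's
#'   score polarity; unnamed scalar applies to all programs.
#' @param top_pct_shared,top_pct_fallback,min_programs See
#'   [pipeline_config()].
#' @return Data.frame: `mirna`, `gene`, `n_programs` (programs keeping the
#'   gene in their top slice), `tag` (`"shared"` or `"fallback"`).
#' @export
consensus_targets <- function(scores, higher_is_better = TRUE,
                              top_pct_shared = 0.05,
                              top_pct_fallback = 0.01,
                              min_programs = 2L) {
  need <- c("program", "mirna", "gene", "score")
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  if (anyDuplicated(scores[c("program", "mirna", "gene")]))
    stop("(program, mirna, gene) must be unique", call. = FALSE)
  programs <- unique(scores$program)
  if (is.null(names(higher_is_better))) {
    if (length(higher_is_better) != 1L)
      stop("unnamed 'higher_is_better' must be a scalar", call. = FALSE)
    higher_is_better <- stats::setNames(rep(higher_is_better,
                                            length(programs)), programs)
  }
  missing_pol <- setdiff(programs, names(higher_is_better))
  if (length(missing_pol))
    stop("unknown score polarity for program(s): ",
         paste(missing_pol, collapse = ", "), call. = FALSE)

  key <- paste(scores$program, scores$mirna, sep = "\r")
  pieces <- split(scores, key)
  ranked <- lapply(pieces, function(d) {
    hib <- higher_is_better[[d$program[1]]]
    s <- if (hib) -d$score else d$score
    ord <- order(s, d$gene)
    d <- d[ord, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d$n_scored <- nrow(d)
    d
  })
  ranked <- do.call(rbind, ranked)
  ranked$in_shared <- ranked$rank <= ceiling(top_pct_shared * ranked$n_scored)
  ranked$in_fallback <- ranked$rank <=
    ceiling(top_pct_fallback * ranked$n_scored)

  out <- lapply(split(ranked, ranked$mirna), function(d) {
    top <- d[d$in_shared, , drop = FALSE]
    support <- table(top$gene)
    shared <- names(support)[support >= min_programs]
    if (length(shared)) {
      data.frame(mirna = d$mirna[1], gene = sort(shared),
                 n_programs = as.integer(support[sort(shared)]),
                 tag = "shared", stringsAsFactors = FALSE)
    } else {
      fb <- d[d$in_fallback, , drop = FALSE]
      if (!nrow(fb)) return(NULL)
      support_fb <- table(fb$gene)
      data.frame(mirna = d$mirna[1], gene = sort(names(support_fb)),
                 n_programs = as.integer(support_fb[sort(names(support_fb))]),
                 tag = "fallback", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(mirna = character(), gene = character(),
                      n_programs = integer(), tag = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shared-target grouping of co-regulated miRNAs
#'
#' For every unordered pair of miRNAs whose differential-expression fold
#' changes share the same sign, counts the genes their target sets have in
#' common, then reports connected components over pairs sharing at least
#' `min_shared` genes.
#'
#' @param targets Target table from [consensus_targets()].
#' @param de DE table with `mirna` and `log2_fc` columns.
#' @param min_shared Minimum common-gene count for an edge (default 1).
#' @return List with `pairs` (data.frame `mirna1`, `mirna2`, `direction`,
#'   `n_common`) and `components` (list of same-direction miRNA groups of
#'   size >= 2).
#' @export
shared_target_graph <- function(targets, de, min_shared = 1L) {
  stopifnot(is.data.frame(targets), is.data.frame(de))
  mirnas <- sort(unique(targets$mirna))
  missing_de <- setdiff(mirnas, de$mirna)
  if (length(missing_de))
    stop("no DE direction for miRNA(s): ",
         paste(missing_de, collapse = ", "), call. = FALSE)
  dir <- sign(de$log2_fc)[match(mirnas, de$mirna)]
  sets <- lapply(mirnas, function(m) unique(targets$gene[targets$mirna == m]))
  names(sets) <- mirnas
  pairs <- NULL
  if (length(mirnas) >= 2L) {
    cmb <- utils::combn(seq_along(mirnas), 2L)
    same <- dir[cmb[1, ]] == dir[cmb[2, ]] & dir[cmb[1, ]] != 0
    n_common <- vapply(seq_len(ncol(cmb)), function(k)
      length(intersect(sets[[cmb[1, k]]], sets[[cmb[2, k]]])), integer(1))
    keep <- same
    pairs <- data.frame(mirna1 = mirnas[cmb[1, keep]],
                        mirna2 = mirnas[cmb[2, keep]],
                        direction = ifelse(dir[cmb[1, keep]] > 0, "up", "down"),
                        n_common = n_common[keep],
                        stringsAsFactors = FALSE)
  }
  if (is.null(pairs))
    pairs <- data.frame(mirna1 = character(), mirna2 = character(),
                        direction = character(), n_common = integer(),
                        stringsAsFactors = FALSE)
  edges <- pairs[pairs$n_common >= min_shared, , drop = FALSE]
  comps <- list()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[c("mirna1", "mirna2")],
                                       directed = FALSE)
    mem <- igraph::components(g)$membership
    comps <- unname(split(names(mem), mem))
    comps <- lapply(comps, sort)
    comps <- comps[order(vapply(comps, `[`, "", 1L))]
  }
  list(pairs = pairs, components = comps)
}

#' Hypergeometric pathway over-representation
#'
#' One-sided hypergeometric tail test of the overlap between a gene set
#' and each pathway, within a stated gene universe, with BH adjustment
#' across pathways.
#'
#' @param gene_set Character vector of genes of interest (must lie in the
#'   universe).
#' @param pathways Named list of character vectors (pathway gene sets).
#' @param universe Character vector: all genes that could have been
#'   selected.
#' @return Data.frame: `pathway`, `overlap`, `pathway_size`,
#'   `gene_set_size`, `universe_size`, `pvalue`, `padj`.
#' @export
pathway_enrichment <- function(gene_set, pathways, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene set contains genes outside the universe", call. = FALSE)
  N <- length(universe)
  k <- length(gene_set)
  res <- lapply(names(pathways), function(pw) {
    genes <- intersect(unique(pathways[[pw]]), universe)
    m <- length(genes)
    x <- length(intersect(gene_set, genes))
    # P(X >= x) for X ~ Hypergeom(m successes, N - m failures, k draws)
    p <- stats::phyper(x - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = x, pathway_size = m,
               gene_set_size = k, universe_size = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$pvalue)
  res[order(res$pvalue, res$pathway), , drop = FALSE]
}

#' Spearman concordance between tissue counts and cell-line Ct values
#'
#' Rank correlation (midranks for ties) between sequencing read counts in
#' tissue and qPCR Ct cycles in a cell line for the same miRNAs. Because
#' Ct falls as expression rises, concordant expression yields a negative
#' rho. Non-detected Ct values are assigned the detection ceiling (default
#' 40 cycles) before ranking.
#'
#' @param counts Named numeric vector of per-miRNA read counts.
#' @param ct Named numeric vector of per-miRNA Ct values (`NA` =
#'   not detected).
#' @param ct_ceiling Ct assigned to non-detected assays (default 40).
#' @return List with `rho`, `pvalue` and `n`.
#' @export
tissue_cellline_correlation <- function(counts, ct, ct_ceiling = 40) {
  shared <- intersect(names(counts), names(ct))
  if (length(shared) < 4L)
    stop("need at least 4 paired observations", call. = FALSE)
  x <- counts[shared]
  y <- ct[shared]
  y[is.na(y)] <- ct_ceiling
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), pvalue = ht$p.value, n = length(shared))
}
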