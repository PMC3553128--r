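make_scores <- function(n_genes = 100, programs = c("pA", "pB", "pC"),
                        mirna = "mirX", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(programs, function(pg)
    data.frame(program = pg, mirna = mirna,
               gene = sprintf("g%03d", seq_len(n_genes)),
               score = runif(n_genes), stringsAsFactors = FALSE)))
}

test_that("shared targets need the top slice of at least two programs", {
  sc <- make_scores()
  # force g001 into the top 5% (ceil(0.05*100)=5) of exactly two programs,
  # g002 into the top of exactly one
  sc$score[sc$program == "pA" & sc$gene == "g001"] <- 2
  sc$score[sc$program == "pB" & sc$gene == "g001"] <- 2
  sc$score[sc$program == "pC" & sc$gene == "g002"] <- 2
  tg <- consensus_targets(sc)
  expect_true("g001" %in% tg$gene[tg$tag == "shared"])
  expect_false("g002" %in% tg$gene)
  # a miRNA with shared genes never reports fallback genes
  expect_identical(unique(tg$tag), "shared")
})

test_that("fallback uses the top 1% of any single program", {
  sc <- make_scores(n_genes = 200, programs = "pOnly")
  tg <- consensus_targets(sc)
  expect_identical(unique(tg$tag), "fallback")
  # ceil(0.01 * 200) = 2 genes
  expect_equal(nrow(tg), 2L)
  ord <- order(-sc$score, sc$gene)
  expect_setequal(tg$gene, sc$gene[ord][1:2])
})

test_that("selection is rank-based: invariant under monotone score transforms", {
  sc <- make_scores(seed = 5)
  tg1 <- consensus_targets(sc)
  sc2 <- sc
  sel <- sc2$program == "pB"
  sc2$score[sel] <- exp(3 * sc2$score[sel]) + 7   # strictly increasing
  expect_identical(consensus_targets(sc2), tg1)
  # polarity flip: lower-is-better with negated scores gives the same set
  sc3 <- sc
  sc3$score <- -sc3$score
  tg3 <- consensus_targets(sc3, higher_is_better = FALSE)
  expect_identical(tg3, tg1)
})

test_that("tightening the shared percentile never adds shared genes", {
  sc <- do.call(rbind, lapply(sprintf("mir%02d", 1:4), function(m)
    make_scores(mirna = m, seed = match(m, sprintf("mir%02d", 1:4)))))
  wide <- consensus_targets(sc, top_pct_shared = 0.10)
  narrow <- consensus_targets(sc, top_pct_shared = 0.05)
  w_shared <- wide[wide$tag == "shared", c("mirna", "gene")]
  n_shared <- narrow[narrow$tag == "shared", c("mirna", "gene")]
  expect_true(all(paste(n_shared$mirna, n_shared$gene) %in%
                    paste(w_shared$mirna, w_shared$gene)))
})

test_that("shared-target graph groups same-direction miRNAs by common genes", {
  targets <- data.frame(
    mirna = c("d1", "d1", "d2", "d2", "d3", "u1", "u2"),
    gene = c("gA", "gB", "gA", "gC", "gA", "gB", "gZ"),
    n_programs = 2L, tag = "shared", stringsAsFactors = FALSE)
  de <- data.frame(mirna = c("d1", "d2", "d3", "u1", "u2"),
                   log2_fc = c(-3, -4, -2, 5, 4), stringsAsFactors = FALSE)
  gr <- shared_target_graph(targets, de)
  # three down-regulated miRNAs share gA -> one component of size 3
  expect_true(any(vapply(gr$components, identical, logical(1),
                         y = c("d1", "d2", "d3"))))
  # u1 shares gB with d1 but directions differ: no edge, no mixed component
  expect_false(any(vapply(gr$components, function(cc)
    any(c("u1", "u2") %in% cc) && any(c("d1", "d2", "d3") %in% cc),
    logical(1))))
  # u1/u2 share no gene: no up-regulated component
  expect_false(any(vapply(gr$components, function(cc)
    all(c("u1", "u2") %in% cc), logical(1))))

  # randomized instances match a brute-force pairwise intersection
  set.seed(13)
  for (rep in 1:5) {
    mir <- sprintf("m%02d", 1:8)
    tg <- do.call(rbind, lapply(mir, function(m)
      data.frame(mirna = m,
                 gene = sample(sprintf("g%02d", 1:15), sample(2:6, 1)),
                 n_programs = 2L, tag = "shared",
                 stringsAsFactors = FALSE)))
    de_r <- data.frame(mirna = mir, log2_fc = sample(c(-2, 2), 8, TRUE),
                       stringsAsFactors = FALSE)
    gr <- shared_target_graph(tg, de_r, min_shared = 1L)
    for (k in seq_len(nrow(gr$pairs))) {
      row <- gr$pairs[k, ]
      g1 <- tg$gene[tg$mirna == row$mirna1]
      g2 <- tg$gene[tg$mirna == row$mirna2]
      expect_equal(row$n_common, length(intersect(g1, g2)))
      expect_identical(
        row$direction,
        if (de_r$log2_fc[de_r$mirna == row$mirna1] > 0) "up" else "down")
    }
    # symmetry: miRNA input order does not change the components
    gr2 <- shared_target_graph(tg[sample(nrow(tg)), ], de_r)
    expect_identical(gr2$components, gr$components)
  }
})

test_that("pathway enrichment equals the enumerated hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  pw <- list(hit = universe[1:10], cold = universe[51:90])
  res <- pathway_enrichment(universe[1:10], pw, universe)
  # identical 10-gene set and pathway in a universe of 100: minimal p
  expect_equal(res$pvalue[res$pathway == "hit"], 1 / choose(100, 10),
               tolerance = 1e-10)
  expect_equal(res$pathway[1], "hit")
  expect_gt(res$pvalue[res$pathway == "cold"], 0.99)

  set.seed(17)
  for (rep in 1:10) {
    N <- sample(15:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    gs <- sample(uni, sample(3:8, 1))
    pws <- list(a = sample(uni, sample(3:10, 1)),
                b = sample(uni, sample(3:10, 1)))
    res <- pathway_enrichment(gs, pws, uni)
    for (pw_name in c("a", "b")) {
      r <- res[res$pathway == pw_name, ]
      expect_equal(r$pvalue,
                   oracle_hyper_tail(r$overlap, r$pathway_size,
                                     N - r$pathway_size, r$gene_set_size),
                   tolerance = 1e-10)
    }
    expect_equal(res$padj, oracle_bh(res$pvalue), tolerance = 1e-12)
  }
  expect_error(pathway_enrichment("x", list(), character(0)), "universe")
})

test_that("tissue/cell-line correlation uses midranks and the right sign", {
  counts <- c(m1 = 100, m2 = 500, m3 = 2000, m4 = 9000, m5 = 40)
  ct_inv <- c(m1 = 30, m2 = 27, m3 = 22, m4 = 18, m5 = 33)
  expect_equal(tissue_cellline_correlation(counts, ct_inv)$rho, -1)
  expect_equal(tissue_cellline_correlation(counts, -ct_inv + 60)$rho, 1)

  # 8-point set with a tie checked against the midrank oracle
  x <- c(5, 17, 17, 2, 90, 33, 12, 60)
  y <- c(31, 28, 28, 39, 19, 24, 30, 21)
  names(x) <- names(y) <- paste0("m", 1:8)
  got <- tissue_cellline_correlation(x, y)
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)

  # non-detected Ct values take the ceiling before ranking
  y2 <- y; y2[1] <- NA
  got2 <- tissue_cellline_correlation(x, y2, ct_ceiling = 40)
  y3 <- y; y3[1] <- 40
  expect_equal(got2$rho, oracle_spearman(x, y3), tolerance = 1e-12)

  expect_error(
    tissue_cellline_correlation(counts, setNames(rep(5, 5), names(counts))),
    "constant")
  expect_error(tissue_cellline_correlation(counts[1:3], ct_inv[1:3]),
               "4 paired")
})
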