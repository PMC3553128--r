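test_that("generators are pure functions of their seed", {
  r1 <- make_reference(10, seed = 6)
  r2 <- make_reference(10, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(make_reference(10, seed = 7)$hairpins, r1$hairpins))

  c1 <- simulate_counts(50, fc = c(3, -3), seed = 12)
  c2 <- simulate_counts(50, fc = c(3, -3), seed = 12)
  expect_identical(c1, c2)

  truth <- matrix(rep(c(0, 2), c(4, 4)), ncol = 1,
                  dimnames = list(paste0("p", 1:8), "mA"))
  x1 <- simulate_ct(truth, rep(c("g1", "g2"), each = 4), seed = 3)
  x2 <- simulate_ct(truth, rep(c("g1", "g2"), each = 4), seed = 3)
  expect_identical(x1, x2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(d1, seed = 4, n_hairpins = 5, qpcr_n1 = 6, qpcr_n2 = 6,
                   fc = c(4, -4))
  simulate_dataset(d2, seed = 4, n_hairpins = 5, qpcr_n1 = 6, qpcr_n2 = 6,
                   fc = c(4, -4))
  for (f in c("hairpins.fa", "matures.tsv", "s01.fastq", "ct_table.csv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("reference structure: bounds, arms, pairwise-distinct matures", {
  ref <- make_reference(20, seed = 8)
  lens <- nchar(ref$hairpins)
  expect_true(all(lens >= 70 & lens <= 90))
  mat <- ref$matures
  mlen <- mat$end - mat$start + 1L
  expect_true(all(mlen >= 20 & mlen <= 23))
  expect_true(all(mat$start >= 1L &
                    mat$end <= lens[mat$hairpin_id]))
  # all mature regions pairwise > 3 mismatches apart (shared prefix)
  seqs <- mature_sequences(ref)
  for (i in seq_along(seqs))
    for (j in seq_len(i - 1L)) {
      L <- min(nchar(seqs[i]), nchar(seqs[j]))
      d <- sum(strsplit(substr(seqs[[i]], 1, L), "")[[1]] !=
                 strsplit(substr(seqs[[j]], 1, L), "")[[1]])
      expect_gt(d, 3)
    }
  expect_error(simulate_reads(ref, matrix(1L, 1, 1,
                                          dimnames = list(mat$mature_id[1],
                                                          "s1")),
                              adapter = "CGCAT"), "6 nt")
})

test_that("read simulation round-trips losslessly at zero error rate", {
  ref <- make_reference(6, seed = 14)
  mats <- ref$matures$mature_id
  set.seed(14)
  truth <- matrix(rpois(length(mats) * 2, 6), nrow = length(mats),
                  dimnames = list(mats, c("s1", "s2")))
  storage.mode(truth) <- "integer"
  adapter <- "CGCCTTGGCCGTACAGCAG"
  reads <- simulate_reads(ref, truth, adapter, error_rate = 0, seed = 15)
  expect_identical(attr(reads, "truth"), truth)
  expect_equal(vapply(reads, nrow, integer(1)),
               colSums(truth), ignore_attr = TRUE)
  expect_true(all(nchar(reads$s1$sequence) == 35L))

  cat_all <- do.call(rbind, lapply(names(reads), function(smp) {
    tr <- trim_reads(reads[[smp]], adapter)
    cc <- categorize_reads(tr[tr$kept, ], ref, list(), pipeline_config())
    cc$sample_id <- smp
    cc
  }))
  counts <- build_count_matrix(cat_all, colnames(truth), ref)
  expect_equal(unclass(counts)[, ], unclass(truth)[, ])
})

test_that("most reads survive a 1% error rate and map to the true mature", {
  ref <- make_reference(8, seed = 20)
  mats <- ref$matures$mature_id
  truth <- matrix(20L, nrow = length(mats), ncol = 1,
                  dimnames = list(mats, "s1"))
  adapter <- "CGCCTTGGCCGTACAGCAG"
  reads <- simulate_reads(ref, truth, adapter, error_rate = 0.01, seed = 21)
  tr <- trim_reads(reads$s1, adapter)
  cc <- categorize_reads(tr[tr$kept, ], ref, list(), pipeline_config())
  assigned <- cc$category == "mirna_mm01"
  expect_gte(mean(assigned), 0.95)
  # reads are emitted mature-by-mature in truth row order, so the true
  # mature of each read is reconstructible from the truth counts
  true_mature <- rep(rownames(truth), truth[, 1])
  kept_true <- true_mature[tr$kept]
  agree <- cc$mature_id[assigned] == kept_true[assigned]
  expect_gte(mean(agree), 0.99)
})

test_that("count model limits: Poisson variance and null calibration", {
  c0 <- simulate_counts(400, n_group1 = 25L, n_group2 = 25L, fc = 0,
                        dispersion = 0, base_mean_range = c(100, 100),
                        seed = 30)
  norm <- normalize_counts(c0, attr(c0, "truth")$size_factors)
  vm <- apply(norm, 1, var) / rowMeans(norm)
  # variance/mean ratio concentrates near 1 in the Poisson limit
  expect_lt(abs(median(vm) - 1), 0.15)

  cnull <- simulate_counts(800, fc = 0, dispersion = 0.1, seed = 31)
  de <- differential_expression(cnull, attr(cnull, "groups"))
  expect_gte(mean(de$pvalue < 0.05), 0.01)
  expect_lte(mean(de$pvalue < 0.05), 0.09)
})

test_that("Ct generator: detection floor and exact zero-noise recovery", {
  truth <- matrix(c(rep(0, 5), rep(3, 6), rep(-25, 11)), ncol = 2,
                  dimnames = list(sprintf("p%02d", 1:11), c("mA", "mDim")))
  groups <- rep(c("GERD", "BE"), c(5, 6))
  ct <- simulate_ct(truth, groups, sigma = 0, seed = 40)
  # mDim sits far below the detection floor: all ND
  expect_true(all(is.na(ct$ct[, "mDim"])))
  res <- qpcr_group_test(ddct(ct))
  expect_false(res$evaluable[res$mirna == "mDim"])
  expect_equal(res$log2_fc[res$mirna == "mA"], 3)
})

test_that("the on-disk bundle is complete and internally consistent", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(d, seed = 5, n_hairpins = 6, fc = c(5, -5),
                          qpcr_n1 = 8, qpcr_n2 = 8)
  for (f in c("hairpins.fa", "matures.tsv", "decoy_ncrna.fa",
              "decoy_genome.fa", "decoy_contaminant.fa", "groups.tsv",
              "ct_table.csv", "target_scores.tsv", "pathways.tsv",
              "truth.json"))
    expect_true(file.exists(file.path(d, f)))
  ref <- read_hairpin_reference(file.path(d, "hairpins.fa"),
                                file.path(d, "matures.tsv"))
  expect_identical(ref$hairpins, sim$reference$hairpins)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$seed, 5)
  expect_identical(names(truth$fc), ref$matures$mature_id)
})
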