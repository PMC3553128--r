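cfg <- pipeline_config()

test_that("align_hamming matches an exhaustive all-offsets scan", {
  set.seed(101)
  for (rep in 1:20) {
    refs <- setNames(
      vapply(1:10, function(i)
        paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
              collapse = ""), ""),
      sprintf("h%02d", 1:10))
    read <- paste(sample(c("A", "C", "G", "T", "N"), 20, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                  collapse = "")
    for (mm in 0:3) {
      got <- align_hamming(read, refs, mm)
      want <- oracle_hamming_scan(read, refs, mm)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("placements respect the one-mismatch boundary and full-length fit", {
  ref <- c(h1 = "AAAACGTACGTACGTACGTTTTTT")
  sub <- substr(ref[[1]], 5, 19)
  expect_equal(align_hamming(sub, ref, 0)$start, 4L)
  two_off <- mutate_seq(sub, c(2, 9), c("T", "A"))
  expect_equal(nrow(align_hamming(two_off, ref, 1)), 0L)
  expect_gt(nrow(align_hamming(two_off, ref, 2)), 0L)
  # longer than the reference: empty result, not an error
  expect_equal(nrow(align_hamming(strrep("ACGT", 10), ref, 3)), 0L)
})

test_that("mature assignment enforces the 7-nt overlap and multi-mature discard", {
  ref <- tiny_reference()
  # m1-5p spans hairpin positions 6..27 (1-based). A read placed so that it
  # overlaps m1-5p by exactly 7 nt starts at 0-based offset 20 - 15... use
  # interval arithmetic: read [s, s+L) vs mature [5, 27) 0-based.
  L <- 15L
  aln <- list(target_id = "hp1", start = 20L)   # overlap = 27 - 20 = 7
  expect_identical(assign_to_mature(aln, ref, L, 7L), "m1-5p")
  aln <- list(target_id = "hp1", start = 21L)   # overlap = 6
  expect_identical(assign_to_mature(aln, ref, L, 7L), NA_character_)
  # loop-spanning read reaching both arms by >= 7 nt:
  # read [20, 42) overlaps m1-5p [5,27) by 7 and m1-3p [35,57) by 7
  aln <- list(target_id = "hp1", start = 20L)
  expect_identical(assign_to_mature(aln, ref, 22L, 7L), "ambiguous")
})

test_that("the cascade stops at the first matching tier", {
  ref <- tiny_reference()
  m1 <- substr(ref$hairpins[["hp1"]], 6, 27)
  decoys <- list(ncrna = c(nc1 = paste0("TTTT", m1, "GGGG")),
                 genome = c(g1 = strrep("CA", 40)))
  # read matches both the hairpin (tier 1) and the ncRNA decoy: tier 1 wins
  out <- categorize_reads(
    data.frame(read_id = "r1", sequence = m1, stringsAsFactors = FALSE),
    ref, decoys, cfg)
  expect_identical(out$category, "mirna_mm01")
  expect_identical(out$mature_id, "m1-5p")
  # removing the hairpin match (unmatchable read) falls through to decoys
  out <- categorize_reads(
    data.frame(read_id = "r2", sequence = strrep("CA", 10),
               stringsAsFactors = FALSE), ref, decoys, cfg)
  expect_identical(out$category, "genome")
})

test_that("2-3 mismatch hairpin hits are excluded, worse ones unmapped", {
  ref <- tiny_reference()
  m1 <- substr(ref$hairpins[["hp1"]], 6, 27)
  two_off <- mutate_seq(m1, c(3, 10), c("T", "T"))
  stopifnot(nchar(two_off) == nchar(m1))
  out <- categorize_reads(
    data.frame(read_id = c("a", "b"),
               sequence = c(two_off, mutate_seq(m1, c(1, 5, 9, 13),
                                                c("T", "A", "T", "A"))),
               stringsAsFactors = FALSE),
    ref, list(), cfg)
  expect_identical(out$category, c("mirna_mm23_excluded", "unmapped"))
})

test_that("whole-module agreement with the exhaustive scorer on random instances", {
  set.seed(77)
  n_instances <- 12
  for (inst in seq_len(n_instances)) {
    ref <- make_reference(sample(4:8, 1), seed = 1000 + inst)
    decoys <- list(
      ncrna = setNames(paste(sample(c("A", "C", "G", "T"), 90,
                                    replace = TRUE), collapse = ""), "nc1"),
      genome = setNames(paste(sample(c("A", "C", "G", "T"), 150,
                                     replace = TRUE), collapse = ""), "g1"))
    mats <- mature_sequences(ref)
    seqs <- vapply(1:30, function(i) {
      base <- sample(mats, 1)
      n_err <- sample(0:4, 1, prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
      if (n_err == 0) return(base)
      pos <- sample(nchar(base), n_err)
      mutate_seq(base, pos, sample(c("A", "C", "G", "T"), n_err,
                                   replace = TRUE))
    }, "")
    reads <- data.frame(read_id = sprintf("r%02d", seq_along(seqs)),
                        sequence = seqs, stringsAsFactors = FALSE)
    got <- categorize_reads(reads, ref, decoys, cfg)
    for (k in seq_len(nrow(reads))) {
      want <- oracle_categorize(seqs[k], ref, decoys, cfg)
      expect_identical(got$category[k], want$category)
      expect_identical(got$mature_id[k], want$mature)
    }
  }
})

test_that("count matrix equals generator truth and obeys its contracts", {
  ref <- make_reference(8, seed = 5)
  mats <- ref$matures$mature_id
  set.seed(5)
  truth <- matrix(rpois(length(mats) * 3, 8), nrow = length(mats),
                  dimnames = list(mats, c("s1", "s2", "s3")))
  storage.mode(truth) <- "integer"
  adapter <- "CGCCTTGGCCGTACAGCAG"
  reads <- simulate_reads(ref, truth, adapter, error_rate = 0, seed = 6)
  cat_all <- do.call(rbind, lapply(names(reads), function(smp) {
    tr <- trim_reads(reads[[smp]], adapter)
    cc <- categorize_reads(tr[tr$kept, ], ref, list(), cfg)
    cc$sample_id <- smp
    cc
  }))
  counts <- build_count_matrix(cat_all, c("s1", "s2", "s3"), ref)
  expect_equal(unclass(counts)[, ], unclass(truth)[, ])
  # unknown sample id is an error
  bad <- cat_all; bad$sample_id[1] <- "sX"
  expect_error(build_count_matrix(bad, c("s1", "s2", "s3"), ref), "sX")
})

test_that("category partition and cascade masking hold", {
  ref <- make_reference(5, seed = 9)
  mats <- mature_sequences(ref)
  set.seed(9)
  seqs <- c(unname(mats),
            vapply(1:10, function(i) {
              base <- sample(mats, 1)
              mutate_seq(base, sample(nchar(base), 3),
                         sample(c("A", "C", "G", "T"), 3, replace = TRUE))
            }, ""),
            vapply(1:5, function(i)
              paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = ""), ""))
  reads <- data.frame(read_id = sprintf("r%02d", seq_along(seqs)),
                      sequence = seqs, stringsAsFactors = FALSE)
  decoys <- list(ncrna = c(nc1 = paste0("AAAA", seqs[length(seqs)], "TTTT")))
  full <- categorize_reads(reads, ref, decoys, cfg)
  expect_equal(sum(category_summary(full)$reads), nrow(reads))
  # deleting the ncRNA tier can only move reads to later tiers
  nodecoy <- categorize_reads(reads, ref, list(), cfg)
  t1 <- full$category %in% c("mirna_mm01", "ambiguous_mature")
  expect_identical(full$category[t1], nodecoy$category[t1])
  expect_true(all(nodecoy$category[full$category == "ncrna"] %in%
                    c("mirna_mm23_excluded", "unmapped")))
})
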