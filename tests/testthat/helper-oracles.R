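# Independent brute-force oracles, deliberately written as directly as
# possible (character-by-character scans, explicit sorts, full
# enumerations) so they share no code path with the package.

oracle_hamming_scan <- function(read, refs, max_mm) {
  rch <- strsplit(toupper(read), "")[[1]]
  out <- list()
  for (id in names(refs)) {
    ref <- strsplit(toupper(refs[[id]]), "")[[1]]
    L <- length(rch); M <- length(ref)
    if (L > M) next
    for (off in 0:(M - L)) {
      window <- ref[(off + 1):(off + L)]
      mm <- sum(window != rch | rch == "N" | window == "N")
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(target_id = id, start = off,
                                              mismatches = mm,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(target_id = character(), start = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab[order(tab$mismatches, tab$target_id, tab$start), , drop = FALSE]
}

# Full re-derivation of the cascade category and mature assignment for a
# single read, using oracle_hamming_scan for every tier.
oracle_categorize <- function(seq, ref, decoys, cfg) {
  hits <- oracle_hamming_scan(seq, ref$hairpins, cfg$max_mm_primary)
  if (nrow(hits)) {
    best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
    L <- nchar(seq)
    assigned <- character(0); ambiguous <- FALSE
    for (k in seq_len(nrow(best))) {
      mat <- ref$matures[ref$matures$hairpin_id == best$target_id[k], ,
                         drop = FALSE]
      ov <- pmin(best$start[k] + L, mat$end) -
        pmax(best$start[k], mat$start - 1L)
      reach <- mat$mature_id[ov >= cfg$min_mature_overlap]
      if (length(reach) >= 2L) ambiguous <- TRUE
      assigned <- union(assigned, reach)
    }
    if (ambiguous || length(assigned) > 1L)
      return(list(category = "ambiguous_mature", mature = NA_character_))
    if (length(assigned) == 1L)
      return(list(category = "mirna_mm01", mature = assigned))
  }
  for (tier in c("ncrna", "genome", "contaminant")) {
    db <- decoys[[tier]]
    if (is.null(db) || !length(db)) next
    if (nrow(oracle_hamming_scan(seq, db, cfg$max_mm_decoy)))
      return(list(category = tier, mature = NA_character_))
  }
  relax <- oracle_hamming_scan(seq, ref$hairpins, cfg$relaxed_mm[2])
  if (nrow(relax) && min(relax$mismatches) >= cfg$relaxed_mm[1])
    return(list(category = "mirna_mm23_excluded", mature = NA_character_))
  list(category = "unmapped", mature = NA_character_)
}

oracle_size_factors <- function(counts) {
  n <- nrow(counts); m <- ncol(counts)
  ref <- numeric(n)
  for (i in seq_len(n)) {
    prod <- 1
    for (j in seq_len(m)) prod <- prod * counts[i, j]
    ref[i] <- prod^(1 / m)
  }
  usable <- which(apply(counts > 0, 1, all))
  s <- numeric(m)
  for (j in seq_len(m)) {
    ratios <- sort(counts[usable, j] / ref[usable])
    k <- length(ratios)
    s[j] <- if (k %% 2 == 1) ratios[(k + 1) / 2] else
      (ratios[k / 2] + ratios[k / 2 + 1]) / 2
  }
  s
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (k in i:m) vals <- c(vals, m / k * p[ord[k]])
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# Hypergeometric upper tail by explicit enumeration of the mass function.
oracle_hyper_tail <- function(x, m, n, k) {
  total <- choose(m + n, k)
  p <- 0
  for (i in max(0, k - n):min(k, m))
    if (i >= x) p <- p + choose(m, i) * choose(n, k - i) / total
  p
}

oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Conditional binomial two-sided p (Poisson limit of the exact NB test):
# given totals kA + kB with success probability sA / (sA + sB), sum the
# probabilities of all splits no more probable than the observed one.
oracle_conditional_binomial <- function(kA, kB, sA, sB) {
  S <- kA + kB
  pr <- sA / (sA + sB)
  dens <- dbinom(0:S, S, pr)
  sum(dens[dens <= dens[kA + 1] * (1 + 1e-7)])
}

random_counts <- function(n, m, lambda = 100) {
  matrix(rpois(n * m, lambda) + 1L, nrow = n,
         dimnames = list(paste0("mir", seq_len(n)),
                         paste0("s", seq_len(m))))
}

tiny_reference <- function() {
  # two hairpins; hp1 carries 5p and 3p arms separated by a loop, hp2 a
  # single 5p arm
  hp1 <- paste0("ACGTA", "CGATCGTACGATTACGGATCAG", "TTTAAACC",
                "GGCATCGATTAGCCGTAAGGTC", "ACGTT")
  hp2 <- paste0("TTGCA", "AGCTTAGCTAACGTGCATCAA", "GGGCCTTAGA",
                "CCAATTGGCAAT")
  hairpin_reference(
    c(hp1 = hp1, hp2 = hp2),
    data.frame(hairpin_id = c("hp1", "hp1", "hp2"),
               mature_id = c("m1-5p", "m1-3p", "m2-5p"),
               start = c(6L, 36L, 6L),
               end = c(27L, 57L, 26L),
               stringsAsFactors = FALSE))
}

random_reference <- function(n_hairpins, seed) {
  make_reference(n_hairpins, seed = seed)
}

mutate_seq <- function(s, positions, bases) {
  ch <- strsplit(s, "")[[1]]
  ch[positions] <- bases
  paste(ch, collapse = "")
}
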