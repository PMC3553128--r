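# Synthetic-data generators. Every generator is a pure function of its
# seed and parameters: a master seed fans out to stage seeds by fixed
# offsets so each stage can be regenerated independently.

.stage_seed <- function(seed, stage) {
  offsets <- c(reference = 101L, reads = 211L, counts = 307L, ct = 401L,
               scores = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.hamming_str <- function(a, b) {
  # over the overlapping prefix when lengths differ
  L <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, L), "")[[1]] != strsplit(substr(b, 1, L), "")[[1]])
}

#' Generate a synthetic hairpin reference
#'
#' Random 70-90-nt precursors, each with a 20-23-nt 5p mature arm near the
#' 5' end and, with probability 0.5, a non-overlapping 3p arm near the 3'
#' end (mimicking miRBase precursor annotations). Mature regions are
#' required to be pairwise distinguishable: Hamming distance > 3 over
#' their shared prefix.
#'
#' @param n_hairpins Number of precursors (>= 1).
#' @param seed Integer seed; the same seed reproduces identical output.
#' @param avoid_motif Optional motif (e.g. the adapter's 6-nt seed) that
#'   must not occur in any hairpin, so simulated inserts can never carry
#'   spurious adapter evidence.
#' @return A [hairpin_reference()].
#' @export
make_reference <- function(n_hairpins, seed = 1L, avoid_motif = NULL) {
  stopifnot(n_hairpins >= 1L)
  set.seed(.stage_seed(seed, "reference"))
  hairpins <- character(0)
  matures <- NULL
  mat_seqs <- character(0)
  attempts <- 0L
  i <- 0L
  while (i < n_hairpins) {
    attempts <- attempts + 1L
    if (attempts > 50L * n_hairpins)
      stop("could not build ", n_hairpins, " hairpins with pairwise ",
           "distinguishable matures; try a smaller n", call. = FALSE)
    hp_len <- sample(70:90, 1L)
    hp <- .rand_dna(hp_len)
    if (!is.null(avoid_motif) && grepl(avoid_motif, hp, fixed = TRUE)) next
    m5_len <- sample(20:23, 1L)
    m5_start <- sample(2:8, 1L)
    m5_end <- m5_start + m5_len - 1L
    rows <- data.frame(hairpin_id = NA_character_,
                       mature_id = NA_character_,
                       start = m5_start, end = m5_end,
                       arm = "5p", stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5) {
      m3_len <- sample(20:23, 1L)
      m3_end <- hp_len - sample(1:5, 1L)
      m3_start <- m3_end - m3_len + 1L
      if (m3_start > m5_end + 4L)  # keep a loop between the arms
        rows <- rbind(rows, data.frame(hairpin_id = NA_character_,
                                       mature_id = NA_character_,
                                       start = m3_start, end = m3_end,
                                       arm = "3p", stringsAsFactors = FALSE))
    }
    cand <- substr(rep(hp, nrow(rows)), rows$start, rows$end)
    ok <- all(vapply(cand, function(cs)
      all(vapply(c(mat_seqs, setdiff(cand, cs)), function(other)
        .hamming_str(cs, other) > 3L, logical(1))), logical(1)))
    if (!ok) next
    i <- i + 1L
    hid <- sprintf("hp-%03d", i)
    rows$hairpin_id <- hid
    rows$mature_id <- sprintf("mir-%03d-%s", i, rows$arm)
    hairpins[hid] <- hp
    mat_seqs <- c(mat_seqs, cand)
    matures <- rbind(matures, rows[c("hairpin_id", "mature_id",
                                     "start", "end")])
  }
  hairpin_reference(hairpins, matures)
}

#' Simulate adapter-contaminated short reads from true mature counts
#'
#' Each read is a mature-arm sequence, optionally shifted by up to
#' `max_offset` nt at each end (staying within the hairpin), followed by
#' the 3' adapter, clipped/padded to `read_len` nt (padding re-uses random
#' bases, mimicking run-off into downstream sequence), with independent
#' per-base substitution errors at `error_rate`.
#'
#' @param reference A [hairpin_reference()].
#' @param true_counts Integer matrix of true read counts, mature x sample
#'   (rownames must be mature ids of `reference`).
#' @param adapter Adapter sequence, at least 6 nt.
#' @param error_rate Substitution probability per base, in `[0, 0.05]`.
#' @param seed Integer seed.
#' @param read_len Raw read length (default 35, short-read small-RNA
#'   chemistry).
#' @param max_offset Maximum end shift in nt (default 0; up to 2 supported).
#' @return Named list of per-sample read-set data.frames (as from
#'   [read_fastq()]), with a `"truth"` attribute carrying `true_counts`.
#' @export
simulate_reads <- function(reference, true_counts, adapter,
                           error_rate = 0, seed = 1L, read_len = 35L,
                           max_offset = 0L) {
  stopifnot(inherits(reference, "hairpin_reference"),
            is.matrix(true_counts),
            all(rownames(true_counts) %in% reference$matures$mature_id))
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]", call. = FALSE)
  if (nchar(adapter) < 6L)
    stop("adapter must be at least 6 nt (shorter adapters can never ",
         "satisfy the trimmer's evidence rule)", call. = FALSE)
  if (max_offset < 0L || max_offset > 2L)
    stop("max_offset must be 0, 1 or 2", call. = FALSE)
  set.seed(.stage_seed(seed, "reads"))
  mat <- reference$matures
  bases <- c("A", "C", "G", "T")
  out <- lapply(colnames(true_counts), function(smp) {
    recs <- list()
    for (mid in rownames(true_counts)) {
      nrd <- true_counts[mid, smp]
      if (nrd == 0L) next
      row <- mat[mat$mature_id == mid, ]
      hp <- reference$hairpins[[row$hairpin_id]]
      for (r in seq_len(nrd)) {
        s0 <- row$start; e0 <- row$end
        if (max_offset > 0L) {
          s0 <- max(1L, s0 + sample(-max_offset:max_offset, 1L))
          e0 <- min(nchar(hp), e0 + sample(-max_offset:max_offset, 1L))
        }
        insert <- substr(hp, s0, e0)
        raw <- paste0(insert, adapter)
        if (nchar(raw) < read_len)
          raw <- paste0(raw, .rand_dna(read_len - nchar(raw)))
        raw <- substr(raw, 1L, read_len)
        if (error_rate > 0) {
          ch <- strsplit(raw, "")[[1]]
          hit <- stats::runif(length(ch)) < error_rate
          if (any(hit))
            ch[hit] <- vapply(ch[hit], function(b)
              sample(setdiff(bases, b), 1L), "")
          raw <- paste(ch, collapse = "")
        }
        recs[[length(recs) + 1L]] <- raw
      }
    }
    n <- length(recs)
    data.frame(read_id = sprintf("%s_read%05d", smp, seq_len(max(n, 0L))),
               sequence = unlist(recs, use.names = FALSE),
               kept = TRUE, reject_reason = "none",
               stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  })
  names(out) <- colnames(true_counts)
  attr(out, "truth") <- true_counts
  out
}

#' Simulate a negative-binomial count matrix with injected fold changes
#'
#' Emulates the study design: two groups (default 5 vs 6 samples),
#' per-sample size factors drawn log-uniform in `[0.5, 2]`, and NB counts
#' with `variance = mu + dispersion * mu^2`. An injected log2 fold change
#' `fc` splits symmetrically about the base mean: group1 mean
#' `base * 2^(-fc/2)`, group2 mean `base * 2^(+fc/2)`; `fc = 0` rows are
#' true nulls.
#'
#' @param n_mirna Number of miRNAs.
#' @param n_group1,n_group2 Group sizes (defaults 5 and 6).
#' @param fc Numeric vector of injected log2 fold changes (group2 vs
#'   group1), recycled to `n_mirna`. Default all zero.
#' @param dispersion NB dispersion alpha (>= 0; 0 = Poisson).
#' @param base_mean_range Range the per-miRNA base means are drawn
#'   uniformly from.
#' @param seed Integer seed.
#' @param group_labels Labels for the two groups (baseline first).
#' @return Integer count matrix with `"groups"` attribute and a
#'   `"truth"` attribute (list: `fc`, `base_mean`, `size_factors`,
#'   `dispersion`, `seed`).
#' @export
simulate_counts <- function(n_mirna, n_group1 = 5L, n_group2 = 6L,
                            fc = 0, dispersion = 0.1,
                            base_mean_range = c(50, 500), seed = 1L,
                            group_labels = c("GERD", "BE")) {
  stopifnot(n_mirna >= 1L, n_group1 >= 2L, n_group2 >= 2L, dispersion >= 0)
  set.seed(.stage_seed(seed, "counts"))
  m <- n_group1 + n_group2
  fc <- rep_len(fc, n_mirna)
  base <- stats::runif(n_mirna, base_mean_range[1], base_mean_range[2])
  s <- exp(stats::runif(m, log(0.5), log(2)))
  groups <- rep(group_labels, c(n_group1, n_group2))
  mu <- outer(base, s) * 2^(outer(fc / 2,
                                  ifelse(groups == group_labels[1], -1, 1)))
  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- matrix(draw(mu), nrow = n_mirna,
                   dimnames = list(sprintf("mir-%03d-5p", seq_len(n_mirna)),
                                   sprintf("s%02d", seq_len(m))))
  storage.mode(counts) <- "integer"
  attr(counts, "groups") <- groups
  attr(counts, "truth") <- list(fc = stats::setNames(fc, rownames(counts)),
                                base_mean = base, size_factors = s,
                                dispersion = dispersion, seed = seed)
  counts
}

#' Simulate a qPCR Ct table from true log2 expression
#'
#' Ct = assay base cycle - log2 expression + per-sample offset (plate/U6
#' loading) + Normal(0, sigma) noise; the reference (U6) assay carries the
#' sample offset only. Expression whose noiseless Ct would exceed the
#' detection floor is emitted as not detected (`NA`).
#'
#' @param truth_log2_expression Matrix, samples x assays: true log2
#'   expression relative to an arbitrary per-assay baseline.
#' @param groups Character vector of group labels, one per sample.
#' @param sigma Ct noise standard deviation (cycles), >= 0.
#' @param seed Integer seed.
#' @param assay_base Base cycle of each test assay at log2 expression 0
#'   (default 28).
#' @param u6_base Base cycle of the reference assay (default 18).
#' @param detection_floor Ct above which an assay is reported not detected
#'   (default 40).
#' @param calibrator_sample Calibrator sample id (default: first sample).
#' @return A [ct_table()] with a `"truth"` attribute.
#' @export
simulate_ct <- function(truth_log2_expression, groups, sigma = 0.5,
                        seed = 1L, assay_base = 28, u6_base = 18,
                        detection_floor = 40,
                        calibrator_sample = NULL) {
  stopifnot(is.matrix(truth_log2_expression), sigma >= 0,
            length(groups) == nrow(truth_log2_expression))
  set.seed(.stage_seed(seed, "ct"))
  n <- nrow(truth_log2_expression)
  samples <- rownames(truth_log2_expression)
  if (is.null(samples))
    samples <- sprintf("p%02d", seq_len(n))
  offset <- stats::rnorm(n, 0, 0.5)  # per-sample plate/loading shift
  ct_clean <- assay_base - truth_log2_expression + offset
  ct <- ct_clean + if (sigma > 0)
    matrix(stats::rnorm(length(ct_clean), 0, sigma), nrow = n) else 0
  ct[ct_clean > detection_floor] <- NA
  u6 <- u6_base + offset + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  ct <- cbind(ct, U6 = u6)
  rownames(ct) <- samples
  if (is.null(calibrator_sample)) calibrator_sample <- samples[1]
  out <- ct_table(ct, groups = stats::setNames(groups, samples),
                  reference_assay = "U6",
                  calibrator_sample = calibrator_sample)
  attr(out, "truth") <- list(log2_expression = truth_log2_expression,
                             sample_offset = offset, sigma = sigma,
                             seed = seed)
  out
}

#' Simulate per-program target-prediction score tables
#'
#' Random gene scores per (program, miRNA), with a configurable number of
#' planted consensus genes forced into the top slice of at least
#' `min_programs` programs for each miRNA.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param n_genes Universe size per program/miRNA.
#' @param programs Program names (default three generic programs).
#' @param n_planted Planted shared targets per miRNA (default 2).
#' @param min_programs Programs supporting each planted target (default 2).
#' @param seed Integer seed.
#' @return List with `scores` (long data.frame) and `planted` (data.frame
#'   mirna/gene truth).
#' @export
simulate_scores <- function(mirnas, n_genes = 200L,
                            programs = c("progA", "progB", "progC"),
                            n_planted = 2L, min_programs = 2L, seed = 1L) {
  stopifnot(length(mirnas) >= 1L, n_genes >= 20L,
            min_programs <= length(programs))
  set.seed(.stage_seed(seed, "scores"))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  out <- list(); planted <- list()
  for (m in mirnas) {
    planted_genes <- sample(genes, n_planted)
    support <- sample(programs, min_programs)
    for (pg in programs) {
      sc <- stats::runif(n_genes)
      names(sc) <- genes
      if (pg %in% support)  # force into the program's top slice
        sc[planted_genes] <- 1 + stats::runif(n_planted)
      out[[length(out) + 1L]] <- data.frame(program = pg, mirna = m,
                                            gene = genes, score = unname(sc),
                                            stringsAsFactors = FALSE)
    }
    planted[[m]] <- data.frame(mirna = m, gene = planted_genes,
                               stringsAsFactors = FALSE)
  }
  list(scores = do.call(rbind, out), planted = do.call(rbind, planted))
}

#' Default injected effect sizes of the synthetic study design
#'
#' The ten log2 fold changes (sequencing scale, group2/group1) used by the
#' default end-to-end simulation: three up-regulated and seven
#' down-regulated miRNAs with magnitudes between about 2.9 and 6.8.
#'
#' @return Numeric vector of length 10.
#' @export
study_fc_profile <- function() {
  c(6.83, 5.85, -4.72, 5.58, -4.73, -6.24, -3.37, -3.66, -2.88, -3.90)
}

#' Simulate a complete input bundle on disk
#'
#' Emits a directory with everything the pipeline consumes: hairpin FASTA
#' + mature annotation TSV, decoy FASTAs, per-sample FASTQ files, group
#' labels, a qPCR Ct CSV, target-prediction score TSV, a pathway gene-set
#' TSV, and a `truth.json` ground-truth bundle.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_hairpins Number of hairpins (default 30; the injected panel
#'   stays a small minority so normalization sees a mostly-null matrix).
#' @param n_group1,n_group2 Sequencing group sizes (defaults 5 and 6).
#' @param fc Injected log2 fold changes for the first `length(fc)`
#'   matures (default [study_fc_profile()]); remaining matures are nulls.
#' @param base_mean Mean read count scale per mature (default 60).
#' @param dispersion NB dispersion for the count model (default 0.1).
#' @param error_rate Per-base read error rate (default 0).
#' @param adapter 3' adapter sequence.
#' @param qpcr_n1,qpcr_n2 qPCR cohort sizes (defaults 40 and 27).
#' @param ct_sigma Ct noise SD in cycles (default 0.5).
#' @return Invisible list of generated paths plus the in-memory truth.
#' @export
simulate_dataset <- function(dir, seed = 1L, n_hairpins = 30L,
                             n_group1 = 5L, n_group2 = 6L,
                             fc = study_fc_profile(), base_mean = 60,
                             dispersion = 0.1, error_rate = 0,
                             adapter = "CGCCTTGGCCGTACAGCAG",
                             qpcr_n1 = 40L, qpcr_n2 = 27L,
                             ct_sigma = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(n_hairpins, seed = seed,
                        avoid_motif = substr(adapter, 1L, 6L))
  matures <- ref$matures$mature_id
  n_mat <- length(matures)
  if (length(fc) > n_mat)
    stop("more injected fold changes than matures", call. = FALSE)
  fc_full <- stats::setNames(c(fc, rep(0, n_mat - length(fc))), matures)

  m <- n_group1 + n_group2
  samples <- sprintf("s%02d", seq_len(m))
  groups <- rep(c("GERD", "BE"), c(n_group1, n_group2))
  set.seed(.stage_seed(seed, "counts"))
  mu <- base_mean * 2^(outer(fc_full / 2,
                             ifelse(groups == "GERD", -1, 1)))
  true_counts <- matrix(
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
    nrow = n_mat, dimnames = list(matures, samples))
  storage.mode(true_counts) <- "integer"

  reads <- simulate_reads(ref, true_counts, adapter,
                          error_rate = error_rate, seed = seed)

  # decoys: unrelated random sequences per tier
  set.seed(.stage_seed(seed, "reference") + 7L)
  decoys <- list(
    ncrna = stats::setNames(vapply(1:5, function(i) .rand_dna(120L), ""),
                            sprintf("ncrna-%02d", 1:5)),
    genome = stats::setNames(vapply(1:3, function(i) .rand_dna(400L), ""),
                             sprintf("chrfrag-%02d", 1:3)),
    contaminant = stats::setNames(.rand_dna(500L), "ecoli-frag-01")
  )

  # qPCR cohort: per-sample true log2 expression = group effect (PCR-scale
  # fold change equals the injected sequencing fold change) + biology noise
  qn <- qpcr_n1 + qpcr_n2
  qgroups <- rep(c("GERD", "BE"), c(qpcr_n1, qpcr_n2))
  assays <- names(fc_full)[seq_len(min(length(fc), n_mat))]
  expr <- outer(ifelse(qgroups == "GERD", -0.5, 0.5),
                fc_full[assays]) + 10
  rownames(expr) <- sprintf("p%02d", seq_len(qn))
  ct <- simulate_ct(expr, qgroups, sigma = ct_sigma, seed = seed)

  sim_sc <- simulate_scores(assays, seed = seed)

  # pathway collection over the score universe, first pathway enriched in
  # the planted targets
  genes <- sort(unique(sim_sc$scores$gene))
  set.seed(.stage_seed(seed, "scores") + 11L)
  pathways <- c(list(PW_PLANTED = unique(c(sim_sc$planted$gene,
                                           sample(genes, 10L)))),
                lapply(stats::setNames(1:4, sprintf("PW_%02d", 1:4)),
                       function(i) sample(genes, 25L)))

  paths <- list(
    hairpin_fasta = file.path(dir, "hairpins.fa"),
    mature_tsv = file.path(dir, "matures.tsv"),
    ncrna_fasta = file.path(dir, "decoy_ncrna.fa"),
    genome_fasta = file.path(dir, "decoy_genome.fa"),
    contaminant_fasta = file.path(dir, "decoy_contaminant.fa"),
    groups_tsv = file.path(dir, "groups.tsv"),
    ct_csv = file.path(dir, "ct_table.csv"),
    scores_tsv = file.path(dir, "target_scores.tsv"),
    gene_sets_tsv = file.path(dir, "pathways.tsv"),
    truth_json = file.path(dir, "truth.json"),
    fastq = stats::setNames(file.path(dir, paste0(samples, ".fastq")),
                            samples)
  )
  write_hairpin_reference(ref, paths$hairpin_fasta, paths$mature_tsv)
  write_fasta(decoys$ncrna, paths$ncrna_fasta)
  write_fasta(decoys$genome, paths$genome_fasta)
  write_fasta(decoys$contaminant, paths$contaminant_fasta)
  for (smp in samples) write_fastq(reads[[smp]], paths$fastq[[smp]])
  write_tsv(data.frame(sample = samples, group = groups), paths$groups_tsv)
  write_ct_table(ct, paths$ct_csv)
  write_tsv(sim_sc$scores, paths$scores_tsv)
  write_tsv(data.frame(
    pathway = rep(names(pathways), lengths(pathways)),
    gene = unlist(pathways, use.names = FALSE)), paths$gene_sets_tsv)

  truth <- list(seed = seed, adapter = adapter, error_rate = error_rate,
                dispersion = dispersion, fc = as.list(fc_full),
                true_counts = as.data.frame(true_counts),
                samples = samples, groups = groups,
                qpcr_groups = qgroups, ct_sigma = ct_sigma,
                planted_targets = sim_sc$planted)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, list(truth = truth, reference = ref, decoys = decoys,
                          true_counts = true_counts, ct = ct,
                          scores = sim_sc$scores, pathways = pathways)))
}
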