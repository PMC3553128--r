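# Two-level group factor preserving the order of first appearance, so the
# baseline (denominator) group is the first one listed, not the
# alphabetically first. Factors passed in keep their declared levels.
.as_group_factor <- function(groups) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  droplevels(groups)
}

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-miRNA pooled within-group moment estimator on normalized counts:
#' with pooled within-group variance v and grand mean m,
#' alpha = max(0, (v - m) / m^2) (variance model mu + alpha * mu^2).
#' Strictly positive estimates below 1e-8 are raised to 1e-8; non-positive
#' estimates (including constant rows) are exactly 0. No trend fitting or
#' shrinkage toward a fitted value is applied.
#'
#' With the handful of replicates typical of these designs the per-miRNA
#' moment estimate is noisy, and rows whose dispersion happens to be
#' underestimated produce spuriously small exact-test p-values. Following
#' the conservative convention of taking each row's dispersion as the
#' maximum of its own estimate and a cohort value, `moderate = TRUE`
#' (default) floors every row at the across-row median estimate; set
#' `moderate = FALSE` for the raw per-row estimator.
#'
#' @param normalized Normalized count matrix, miRNA x samples.
#' @param groups Two-level factor/character vector, one label per sample.
#' @param moderate Floor each row's dispersion at the across-row median
#'   (default `TRUE`).
#' @return Named numeric vector of dispersions, one per miRNA.
#' @export
estimate_dispersion <- function(normalized, groups, moderate = TRUE) {
  stopifnot(is.matrix(normalized), length(groups) == ncol(normalized))
  groups <- .as_group_factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  n_per <- table(groups)
  if (any(n_per < 2L))
    stop("each group needs at least 2 samples for dispersion estimation",
         call. = FALSE)
  g1 <- groups == levels(groups)[1]
  v1 <- apply(normalized[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(normalized[, !g1, drop = FALSE], 1L, stats::var)
  n1 <- sum(g1); n2 <- sum(!g1)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- rowMeans(normalized)
  est <- (v - m) / m^2
  est[!is.finite(est)] <- 0
  alpha <- pmax(est, 0)
  alpha[alpha > 0 & alpha < 1e-8] <- 1e-8
  if (moderate) alpha <- pmax(alpha, stats::median(alpha))
  names(alpha) <- rownames(normalized)
  alpha
}

# Conditional NB exact-test p for one miRNA.
# kA, kB: group-total raw counts; sA, sB: summed size factors; sA2, sB2:
# summed squared size factors; alpha: dispersion. Under the null of a
# common per-unit mean q = (kA+kB)/(sA+sB), the group totals are modeled
# NB with mean q*s and variance q*s + alpha*q^2*s2; the two-sided p sums
# the conditional probabilities of every split (a, S-a) of the observed
# total no more probable than the observed one (ties included).
.nb_exact_p <- function(kA, kB, sA, sB, sA2, sB2, alpha) {
  S <- kA + kB
  if (S == 0L) return(NA_real_)
  q <- S / (sA + sB)
  a <- 0:S
  dens <- function(x, mu, s2sum) {
    v <- mu + alpha * q^2 * s2sum
    if (alpha <= 1e-12 || v <= mu * (1 + 1e-12)) {
      stats::dpois(x, lambda = mu)
    } else {
      stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu))
    }
  }
  pa <- dens(a, q * sA, sA2)
  pb <- dens(S - a, q * sB, sB2)
  pab <- pa * pb
  tot <- sum(pab)
  if (tot <= 0) return(NA_real_)
  pobs <- pab[kA + 1L]
  min(1, sum(pab[pab <= pobs * (1 + 1e-7)]) / tot)
}

#' Negative-binomial exact test for two-group differential expression
#'
#' For each miRNA the test conditions on the pair of group-total raw
#' counts; under the null of equal per-unit means the totals follow
#' negative-binomial laws with means scaled by the summed size factors and
#' variances inflated by the per-miRNA dispersion. The two-sided p-value
#' sums the probabilities of all splits of the observed total that are no
#' more probable than the observed split. Fold changes are ratios of group
#' means of normalized counts, reported as log2(group2 / group1).
#'
#' Rows with zero counts in both groups are dropped before testing and
#' listed in the `"all_zero"` attribute of the result.
#'
#' @param counts Raw integer count matrix, miRNA x samples.
#' @param s Size-factor vector (see [size_factors()]).
#' @param alpha Per-miRNA dispersions (see [estimate_dispersion()]);
#'   recycled if scalar.
#' @param groups Two-level factor; the first level is the baseline
#'   (denominator) group.
#' @param fdr_q FDR level for the significance call (default 0.05).
#' @param low_count_threshold Reads-per-group threshold for the low-count
#'   validation filter (default 25).
#' @return Data.frame (one row per tested miRNA): `mirna`, `mean_norm_1`,
#'   `mean_norm_2`, `log2_fc`, `pvalue`, `padj`, `low_count_flag`,
#'   `significant`. Attribute `"all_zero"` lists dropped miRNA ids.
#' @export
nb_exact_test <- function(counts, s, alpha, groups, fdr_q = 0.05,
                          low_count_threshold = 25L) {
  stopifnot(is.matrix(counts), length(s) == ncol(counts))
  groups <- .as_group_factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(counts))
  if (length(alpha) != nrow(counts))
    stop("dispersion vector length must match row count", call. = FALSE)
  g1 <- groups == levels(groups)[1]
  norm <- normalize_counts(counts, s)
  all_zero <- rowSums(counts) == 0
  keep <- which(!all_zero)

  kA <- rowSums(counts[, g1, drop = FALSE])
  kB <- rowSums(counts[, !g1, drop = FALSE])
  sA <- sum(s[g1]); sB <- sum(s[!g1])
  sA2 <- sum(s[g1]^2); sB2 <- sum(s[!g1]^2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])

  p <- vapply(keep, function(i)
    .nb_exact_p(kA[i], kB[i], sA, sB, sA2, sB2, alpha[i]), numeric(1))
  lfc <- log2(m2[keep] / m1[keep])  # +/-Inf when one group is all zero
  padj <- bh_adjust(p)
  low <- low_count_filter(counts, groups, low_count_threshold)[keep]
  res <- data.frame(
    mirna = rownames(counts)[keep],
    mean_norm_1 = m1[keep],
    mean_norm_2 = m2[keep],
    log2_fc = lfc,
    pvalue = p,
    padj = padj,
    low_count_flag = low,
    significant = !is.na(padj) & padj < fdr_q,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "all_zero") <- rownames(counts)[all_zero]
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that every p-value lies in `[0, 1]` and applies the
#' Benjamini-Hochberg step-up procedure (via `stats::p.adjust`): sorted
#' ascending, the i-th adjusted value is `min over k >= i of (m/k) p_(k)`,
#' capped at 1 and restored to input order.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Low-count validation filter
#'
#' Flags a miRNA when its group-total raw read count is strictly below
#' `threshold` in both groups; such miRNAs are excluded from qPCR
#' validation even when statistically significant.
#'
#' @param counts Raw integer count matrix.
#' @param groups Two-level factor.
#' @param threshold Reads-per-group threshold (default 25).
#' @return Named logical vector, one flag per miRNA.
#' @export
low_count_filter <- function(counts, groups, threshold = 25L) {
  stopifnot(is.matrix(counts))
  groups <- .as_group_factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  g1 <- groups == levels(groups)[1]
  t1 <- rowSums(counts[, g1, drop = FALSE])
  t2 <- rowSums(counts[, !g1, drop = FALSE])
  stats::setNames(t1 < threshold & t2 < threshold, rownames(counts))
}

#' Full differential-expression stage
#'
#' Convenience wrapper: size factors, dispersions and the exact test in
#' one call.
#'
#' @inheritParams nb_exact_test
#' @param groups Two-level factor (defaults to the matrix's `"groups"`
#'   attribute).
#' @return See [nb_exact_test()].
#' @export
differential_expression <- function(counts, groups = attr(counts, "groups"),
                                    fdr_q = 0.05, low_count_threshold = 25L) {
  if (is.null(groups)) stop("no group labels supplied", call. = FALSE)
  s <- size_factors(counts)
  norm <- normalize_counts(counts, s)
  alpha <- estimate_dispersion(norm, groups)
  nb_exact_test(counts, s, alpha, groups, fdr_q = fdr_q,
                low_count_threshold = low_count_threshold)
}
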