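#' Pseudo-reference for median-of-ratios normalization
#'
#' The pseudo-reference value of each miRNA is the geometric mean of its
#' counts across all samples. Rows containing any zero have geometric mean
#' zero and are flagged for exclusion from the median (their ratios are
#' undefined). No pseudocounts are added.
#'
#' @param counts Numeric matrix, miRNA x samples.
#' @return Numeric vector of per-miRNA reference values with a logical
#'   `"excluded"` attribute marking zero-containing rows.
#' @export
pseudo_reference <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  has_zero <- apply(counts == 0, 1L, any)
  if (all(has_zero))
    stop("normalization infeasible: no miRNA with strictly positive ",
         "counts in every sample", call. = FALSE)
  ref <- numeric(nrow(counts))
  # geometric mean in the log domain for numerical stability
  ref[!has_zero] <- exp(rowMeans(log(counts[!has_zero, , drop = FALSE])))
  attr(ref, "excluded") <- has_zero
  names(ref) <- rownames(counts)
  ref
}

#' Median-of-ratios size factors
#'
#' The size factor of sample j is the median over usable miRNAs (those
#' with all-positive counts) of the ratio of the sample's count to the
#' pseudo-reference. An even number of usable rows takes the midpoint of
#' the two central order statistics.
#'
#' @param counts Numeric matrix, miRNA x samples.
#' @return Numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  ref <- pseudo_reference(counts)
  use <- !attr(ref, "excluded")
  ratios <- counts[use, , drop = FALSE] / ref[use]
  s <- apply(ratios, 2L, stats::median)
  if (any(!is.finite(s) | s <= 0))
    stop("non-positive or non-finite size factor", call. = FALSE)
  names(s) <- colnames(counts)
  s
}

#' Normalize a count matrix by per-sample size factors
#'
#' @param counts Numeric matrix, miRNA x samples.
#' @param s Size-factor vector, one positive value per sample.
#' @return Matrix of `counts[, j] / s[j]`, same shape and dimnames, with
#'   the `"groups"` attribute (if any) carried over.
#' @export
normalize_counts <- function(counts, s = size_factors(counts)) {
  stopifnot(is.matrix(counts), length(s) == ncol(counts))
  if (any(!is.finite(s) | s <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  out <- sweep(counts, 2L, s, "/")
  attr(out, "groups") <- attr(counts, "groups")
  out
}
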