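#' Construct a qPCR Ct table
#'
#' Holds cycle-threshold values (samples x assays), the reference assay
#' used for normalization (U6 by default), the single calibrator sample
#' every other sample is compared to, per-sample group labels, and
#' optional minus-RT control Ct values per assay.
#'
#' @param ct Numeric matrix, samples x assays; `NA` marks non-detection.
#' @param groups Named character vector of group labels (names are sample
#'   ids).
#' @param reference_assay Column name of the reference assay.
#' @param calibrator_sample Row name of the calibrator sample.
#' @param minus_rt Optional named numeric vector: minus-RT control Ct per
#'   assay (`NA` = no amplification).
#' @return An object of class `"ct_table"`.
#' @export
ct_table <- function(ct, groups, reference_assay = "U6",
                     calibrator_sample = rownames(ct)[1],
                     minus_rt = NULL) {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  if (!reference_assay %in% colnames(ct))
    stop("reference assay '", reference_assay, "' not present", call. = FALSE)
  if (!calibrator_sample %in% rownames(ct))
    stop("calibrator sample '", calibrator_sample, "' not present",
         call. = FALSE)
  if (!all(rownames(ct) %in% names(groups)))
    stop("every sample needs a group label", call. = FALSE)
  structure(list(ct = ct, groups = groups[rownames(ct)],
                 reference_assay = reference_assay,
                 calibrator_sample = calibrator_sample,
                 minus_rt = minus_rt),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", nrow(x$ct), "samples x", ncol(x$ct), "assays;",
      "reference =", x$reference_assay, "; calibrator =",
      x$calibrator_sample, "\n")
  invisible(x)
}

#' Delta-delta-Ct relative expression
#'
#' Per sample and assay: dCt = Ct_assay - Ct_reference, ddCt = dCt_sample
#' - dCt_calibrator, log2 relative expression = -ddCt (one cycle earlier
#' than the calibrator doubles expression). Non-detected assays yield
#' missing values (never imputed). Samples whose reference assay is not
#' detected are excluded with a warning. Assays whose minus-RT control
#' amplifies within `minus_rt_margin` cycles of the assay's best test well
#' are flagged invalid and dropped.
#'
#' @param x A [ct_table()].
#' @param minus_rt_margin Cycles, default 5.
#' @return Numeric matrix of log2 relative expression (samples x assays,
#'   reference assay column removed), with attributes `"groups"`,
#'   `"calibrator_sample"` and `"invalid_assays"`.
#' @export
ddct <- function(x, minus_rt_margin = 5) {
  stopifnot(inherits(x, "ct_table"))
  ct <- x$ct
  u6 <- ct[, x$reference_assay]
  drop_samples <- rownames(ct)[is.na(u6)]
  if (x$calibrator_sample %in% drop_samples)
    stop("reference assay not detected in the calibrator sample",
         call. = FALSE)
  if (length(drop_samples)) {
    warning("excluding sample(s) with undetected reference assay: ",
            paste(drop_samples, collapse = ", "), call. = FALSE)
    ct <- ct[!rownames(ct) %in% drop_samples, , drop = FALSE]
    u6 <- ct[, x$reference_assay]
  }
  assays <- setdiff(colnames(ct), x$reference_assay)
  invalid <- character(0)
  if (!is.null(x$minus_rt)) {
    for (a in intersect(assays, names(x$minus_rt))) {
      mrt <- x$minus_rt[[a]]
      if (!is.na(mrt) && any(!is.na(ct[, a])) &&
          mrt - min(ct[, a], na.rm = TRUE) < minus_rt_margin)
        invalid <- c(invalid, a)
    }
    assays <- setdiff(assays, invalid)
  }
  dct <- ct[, assays, drop = FALSE] - u6
  ddct <- sweep(dct, 2L, dct[x$calibrator_sample, ], "-")
  rel <- -ddct
  attr(rel, "groups") <- x$groups[rownames(rel)]
  attr(rel, "calibrator_sample") <- x$calibrator_sample
  attr(rel, "invalid_assays") <- invalid
  rel
}

#' Per-assay group comparison of qPCR relative expression
#'
#' Welch two-sample t-test on log2 relative expression per assay; the
#' group fold change is the difference of group means (group2 - group1,
#' log2 scale), so it is directly comparable with the sequencing log2
#' fold change. BH adjustment runs across evaluable assays. Assays with
#' fewer than two detected samples in either group are reported as
#' not-evaluable (ND).
#'
#' @param rel Output of [ddct()].
#' @param groups Two-level factor (defaults to the `"groups"` attribute);
#'   first level is the baseline group.
#' @param fdr_q FDR level for the significance call.
#' @return Data.frame: `mirna`, `log2_fc`, `pvalue`, `padj`, `evaluable`,
#'   `significant`.
#' @export
qpcr_group_test <- function(rel, groups = attr(rel, "groups"), fdr_q = 0.05) {
  stopifnot(is.matrix(rel))
  groups <- .as_group_factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  g1 <- groups == levels(groups)[1]
  res <- lapply(colnames(rel), function(a) {
    x1 <- rel[g1, a]; x2 <- rel[!g1, a]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L)
      return(data.frame(mirna = a, log2_fc = NA_real_, pvalue = NA_real_,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    fc <- mean(x2) - mean(x1)
    # degenerate zero-variance groups: the t statistic is 0/0 (identical
    # means -> no evidence) or infinite (separated means)
    p <- if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else 0
    } else {
      stats::t.test(x2, x1)$p.value
    }
    data.frame(mirna = a, log2_fc = fc, pvalue = p, evaluable = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- NA_real_
  res$padj[res$evaluable] <- bh_adjust(res$pvalue[res$evaluable])
  res$significant <- !is.na(res$padj) & res$padj < fdr_q
  res[c("mirna", "log2_fc", "pvalue", "padj", "evaluable", "significant")]
}

#' Direction concordance between sequencing and qPCR fold changes
#'
#' Over miRNAs evaluated on both platforms (by default restricted to
#' those significant on both), the fraction whose log2 fold changes agree
#' in sign.
#'
#' @param de_ngs Sequencing DE table (see [nb_exact_test()]).
#' @param de_qpcr qPCR result table (see [qpcr_group_test()]).
#' @param validated_only Restrict to miRNAs significant on both platforms
#'   (default `TRUE`).
#' @return A list: `concordance` (fraction in `[0, 1]`), `n` (miRNAs
#'   compared), and the per-miRNA `table` of signs.
#' @export
direction_concordance <- function(de_ngs, de_qpcr, validated_only = TRUE) {
  stopifnot(is.data.frame(de_ngs), is.data.frame(de_qpcr))
  m <- merge(de_ngs[c("mirna", "log2_fc", "significant")],
             de_qpcr[c("mirna", "log2_fc", "significant")],
             by = "mirna", suffixes = c("_ngs", "_qpcr"))
  m <- m[!is.na(m$log2_fc_ngs) & !is.na(m$log2_fc_qpcr), , drop = FALSE]
  if (validated_only)
    m <- m[m$significant_ngs & m$significant_qpcr, , drop = FALSE]
  if (!nrow(m))
    stop("no miRNA shared between the two platforms under the current ",
         "filter", call. = FALSE)
  agree <- sign(m$log2_fc_ngs) == sign(m$log2_fc_qpcr)
  list(concordance = mean(agree), n = nrow(m),
       table = data.frame(mirna = m$mirna,
                          sign_ngs = sign(m$log2_fc_ngs),
                          sign_qpcr = sign(m$log2_fc_qpcr),
                          agree = agree, stringsAsFactors = FALSE))
}
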