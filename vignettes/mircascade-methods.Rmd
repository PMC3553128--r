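---
title: "Methods: cascade miRNA quantification, normalization and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade miRNA quantification, normalization and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

# Scope and model

`mircascade` implements a complete small RNA-seq analysis chain for mature
microRNA quantification and two-group differential expression, of the kind
used to compare gastro-esophageal reflux (GERD) squamous mucosa against
Barrett's esophagus (BE) columnar epithelium: a discovery phase on a small
sequencing cohort (here 5 vs 6 samples), an independent qRT-PCR validation
phase on a larger cohort (40 vs 27), consensus target prediction, and
tissue/cell-line expression concordance. Every stage is driven by explicit,
configurable thresholds (`pipeline_config()`), and a synthetic-data module
generates inputs with known ground truth so the whole chain is testable
offline.

# Read inclusion and adapter trimming

Raw reads are fixed-length (35 nt by default in the simulator) and carry
the 3' sequencing adapter downstream of the biological insert. A read is
included when three conditions hold:

* adapter evidence: at least `min_adapter_match` (default 6) nucleotides of
  the adapter are found in the read. The search is an exact match of the
  adapter's first 6 nt; the leftmost occurrence wins and the read is cut
  immediately before it. Whether the evidence requirement tolerates
  mismatches is not specified by the protocol this models; exact matching
  is the deterministic reading and is declared here as an assumption.
  Reads with no adapter evidence are rejected rather than passed
  untrimmed, because inclusion requires the adaptor to have been seen.
* length: the trimmed insert is at least `min_trimmed_len` (default 15) nt.
* no ambiguity: the trimmed insert contains only A/C/G/T. The check applies
  to the insert only, since the adapter portion is discarded anyway.

Rejection is a categorized outcome (`no_adapter`, `too_short`,
`ambiguous_base`), never an error. Trimming is idempotent on kept reads
and monotone in the length threshold; both properties are tested.

# The sequential mapping cascade

Kept reads pass through reference databases in a fixed order, and a read
is resolved by the first tier that matches it:

1. **miRNA hairpins, at most 1 mismatch.** A placement is valid only when
   the entire read fits consecutively (ungapped, full-length) inside a
   hairpin. `N` in a read matches nothing, including reference `N`.
2. **Mature assignment.** A tier-1 read counts toward a mature arm when
   its placement overlaps that arm's annotated interval by at least
   `min_mature_overlap` (default 7) nt. If two distinct matures reach the
   threshold (a loop-spanning read), the read is *ambiguous* and is never
   counted. Multi-hairpin hits at the best mismatch count that all imply
   the same mature id (paralogous precursors) count once; distinct implied
   matures are discarded as ambiguous — the exclusion rule speaks of
   multiple *mature* miRNAs, not multiple precursors.
3. **Decoy tiers, up to 3 mismatches:** non-miRNA ncRNA, then genome
   fragments, then a contaminant genome. Only the category is recorded;
   mismatch-equal hits to different decoy targets need no resolution.
4. **Relaxed hairpin remap, 2–3 mismatches.** Still-unmatched reads are
   retried on the hairpins; hits with a best mismatch count in {2, 3} are
   categorized `mirna_mm23_excluded` and never contribute to the count
   matrix (reads at ≤1 mismatch were already consumed by tier 1, so the
   window is literally 2–3).
5. Anything left is `unmapped`.

A read that aligns to a hairpin at ≤1 mismatch but overlaps no mature arm
by ≥7 nt fails the mature condition and falls through the cascade like an
unmatched read; this is a deliberate reading of the two-condition rule
(placement *and* overlap) and is the package's own design choice.

Mature-annotation coordinates are 1-based inclusive (the miRBase
convention); all internal arithmetic is 0-based half-open. Matching is
stranded by default (`revcomp = FALSE`), the convention of stranded
small-RNA protocols; a flag enables additional reverse-complement
matching.

The aligner is a vectorized shifted-window Hamming scan, chosen over
index-based tools because the decisive tests compare the whole module
against an exhaustive all-offsets scorer, and because the contracts (full
control of `N` semantics and tie order) are easiest to guarantee in a
transparent implementation. It is intended for the panel-scale references
this package targets, not genome-scale alignment.

# Normalization: median of ratios

With counts $k_{ij}$ (miRNA $i$, sample $j$), the pseudo-reference is the
per-miRNA geometric mean across samples, and the size factor of sample
$j$ is

$$ s_j = \operatorname{median}_{i \in U} \; \frac{k_{ij}}{\left(\prod_m k_{im}\right)^{1/m}} $$

where $U$ is the set of miRNAs with strictly positive counts in every
sample. Rows containing a zero have geometric mean zero, making the ratio
undefined, so they are excluded from the median — the only reading under
which the estimator is computable, and the convention of the package
family this follows. No pseudocounts are added anywhere. An even number
of usable rows takes the midpoint of the two central order statistics.
Normalized counts are $k_{ij}/s_j$; no constraint (such as a unit
geometric mean) is imposed on the factors beyond positivity.

The estimator assumes most miRNAs are not differentially expressed. On a
small panel in which a large fraction of rows carries a true effect with
unbalanced signs, part of the group difference is absorbed into the size
factors; the synthetic defaults keep the injected panel a small minority
(10 of ~45 matures) for this reason, mirroring the real setting
(18 differentially expressed of ~1900 known).

# Differential expression

The test is a conditional negative-binomial exact test in the style of the
classical count-based packages. Dispersion $\alpha$ enters through the
variance model $v = \mu + \alpha\mu^2$.

* **Dispersion.** Per-miRNA pooled within-group method-of-moments on
  normalized counts: $\hat\alpha_i = \max(0, (v_i - m_i)/m_i^2)$ with
  $v_i$ the pooled within-group sample variance and $m_i$ the grand mean.
  Strictly positive estimates below $10^{-8}$ are raised to $10^{-8}$;
  non-positive estimates (constant rows) are exactly zero. No trend is
  fitted. With 5–6 replicates the raw per-row estimate is noisy, and rows
  whose dispersion is underestimated yield spuriously small p-values:
  measured on 2000 all-null rows, the raw estimator gives a 0.070–0.083
  false-positive rate at the 0.05 level and a handful of false BH
  discoveries per run. The default therefore floors every row at the
  across-row median estimate (`moderate = TRUE`), the conservative
  "maximum of the per-gene and a cohort value" convention; this restores
  calibration (0.035–0.048 measured) without trend fitting or shrinkage
  toward a fit. `moderate = FALSE` gives the raw estimator.
* **Test.** For each miRNA the group-total counts $(K_A, K_B)$ are
  conditioned on their sum $S$. Under the null of a common per-unit mean
  $q = S/(s_A + s_B)$ (summed size factors), each group total is modeled
  negative-binomial with mean $q\,s_G$ and variance
  $q\,s_G + \alpha q^2 \sum_{j\in G} s_j^2$. The two-sided p-value sums
  the conditional probabilities of every split $(a, S-a)$ that is no more
  probable than the observed split, ties included (with a $1+10^{-7}$
  relative tolerance against floating-point ties). As $\alpha \to 0$ this
  reduces to the conditional binomial, which the tests verify against an
  independent enumeration.
* **Fold change** is the ratio of group means of normalized counts,
  reported as $\log_2(\text{group2}/\text{group1})$ with the baseline
  group being the first to appear in the label vector. For this design it
  coincides with fitted-mean ratios and is reproducible directly from a
  normalized count table. A group with mean zero yields a signed infinite
  value, carried as non-numeric in output tables.
* **Multiplicity.** Benjamini–Hochberg step-up at `fdr_q` (default 5%),
  delegated to `stats::p.adjust(method = "BH")` after input validation,
  with an independent brute-force step-up as the test oracle.
  Significance means adjusted p below `fdr_q`.
* **Low-count filter.** A miRNA whose raw group-total reads are strictly
  below 25 in *both* groups is flagged; such miRNAs are excluded from
  qPCR validation regardless of significance. Rows all-zero in both
  groups are dropped before testing and reported separately.

# qRT-PCR validation and concordance

Relative expression uses the double-delta cycle-threshold construction
with U6 as the reference assay and a single calibrator sample:
$\Delta Ct = Ct_{\text{assay}} - Ct_{U6}$,
$\Delta\Delta Ct = \Delta Ct_{\text{sample}} - \Delta Ct_{\text{calibrator}}$,
and log2 relative expression $= -\Delta\Delta Ct$, so the calibrator's
fold change is exactly 1 and a one-cycle advance doubles expression.
Per-sample plate offsets cancel through the reference assay; this
invariance is tested. Design choices:

* Non-detected wells are missing values, never imputed as Ct 40 —
  mirroring how undetectable assays are reported as ND rather than
  quantified. A sample whose reference assay is undetected is excluded
  with a warning.
* Group comparison is a Welch two-sample t-test on log2 relative
  expression ("standard t-test" leaves the variance assumption open;
  unequal-variance is the robust default), with BH across assays. The
  group fold change is the difference of group means on the log2 scale —
  identical in log space to a mean of per-sample fold ratios, and
  directly comparable to the sequencing log2 fold change. Assays with
  fewer than two detected samples per group are reported not-evaluable.
  Degenerate zero-variance groups receive p = 1 (equal means) or p = 0
  (separated means) rather than an undefined t statistic.
* Minus-RT controls: an assay whose minus-RT control amplifies within 5
  cycles (configurable) of its best test well is flagged invalid; the
  protocol states the control but no threshold, so the margin is declared
  here.

Direction concordance between platforms is, over miRNAs significant on
both (by default), the fraction whose fold-change signs agree. On
synthetic data with large injected effects this is exactly 1, the
property reported as full consistency between discovery and validation.

# Consensus targets, shared-target groups, pathways, cell lines

* **Consensus rule.** For each (program, miRNA) pair, that program's
  genes are ranked best-first and the top $\lceil 0.05\,N\rceil$ kept; a
  gene kept by ≥2 programs is a shared target. A miRNA with no shared
  gene falls back to genes in the top $\lceil 0.01\,N\rceil$ of any
  single program. Ranking is per-(program, miRNA) — the reading
  consistent with scoring "target genes of the miRNA" — and ties break by
  score then gene id, so the selection is deterministic and invariant
  under strictly monotone transforms of any program's scores. Each
  program declares its score polarity.
* **Shared-target groups.** For each unordered pair of miRNAs with
  equal fold-change sign, the common-target count is computed; connected
  components over pairs sharing at least `min_shared` genes (default 1)
  reproduce the clusters of co-regulated miRNAs with common targets.
* **Pathways.** Over-representation is a one-sided hypergeometric tail
  within the scored-gene universe, BH-adjusted across pathways. The
  original analysis used an interactive network tool whose statistic is
  unstated; the hypergeometric test is the declared replacement.
* **Cell lines.** Tissue/cell-line concordance is the Spearman rank
  correlation (midranks on ties, via `stats::cor.test`) between tissue
  read counts and cell-line Ct values; because Ct falls as expression
  rises, concordant expression yields negative rho. Non-detected Ct
  values are set to the 40-cycle detection ceiling before ranking
  (configurable) — here, unlike the ΔΔCt quantification, a rank for
  "below detection" is required and the ceiling is the natural one.

# Synthetic data: what it emulates, and what it does not

Generators are pure functions of a master seed (fanned out to fixed
per-stage child seeds, so stages regenerate independently) and serialize
their ground truth alongside every dataset.

* `make_reference()`: 70–90-nt precursors with a 20–23-nt 5p arm and,
  with probability 0.5, a 3p arm separated by a loop; mature regions are
  pairwise > 3 mismatches apart so a ≤1-mismatch assignment is
  unambiguous by construction. Hairpins can be constrained to avoid the
  adapter seed so inserts never carry spurious adapter evidence.
* `simulate_reads()`: insert (mature arm, optionally shifted up to 2 nt
  within the hairpin) + adapter, clipped/padded to 35 nt, with uniform
  per-base substitution errors (≤5%).
* `simulate_counts()`: negative-binomial counts at the study design
  (5 vs 6), per-sample size factors log-uniform in [0.5, 2], and injected
  log2 fold changes split symmetrically about the base mean
  ($\mu_{1} = b\,2^{-fc/2}$, $\mu_{2} = b\,2^{+fc/2}$) so large effects
  keep totals bounded. The default injected panel (`study_fc_profile()`)
  is ten effects of magnitudes ≈2.9–6.8, three up and seven down — the
  scale of the validated discovery panel.
* `simulate_ct()`: Ct = assay base − log2 expression + per-sample plate
  offset + Gaussian noise; the U6 row carries the offset only; noiseless
  Ct above 40 cycles is emitted as not-detected.
* `simulate_dataset()` writes the full input bundle (FASTAs, FASTQs,
  annotation/label tables, Ct CSV, score and pathway TSVs, truth JSON).

Not modeled: ligation-chemistry color space, quality scores (all rules
are sequence-only), isomiR end heterogeneity beyond the ±2-nt offsets,
5' adapters, cross-mapping between near-identical paralogs (mature
regions are forced apart), and genome-scale decoys. Passing tests
therefore demonstrate the correctness of the rules and statistics, not
robustness to every artifact of real sequencing data.

# Problem sizes and numerical choices

Test and acceptance runs use panel-scale problems chosen as the smallest
sizes that preserve the study's structure: an end-to-end run with 30
hairpins (~45 matures, ~40k reads, 11 samples), 2000 null rows for
calibration, 200 rows for effect recovery, and 100 random instances for
the exhaustive-oracle alignment comparison. Tolerances: size factors are
checked against a brute-force oracle at 1e-10 relative; probability
computations at 1e-10 to 1e-12; the exact test's tie tolerance is
$1+10^{-7}$ relative. The calibration band asserted for the raw
false-positive rate is [0.03, 0.07] at the 0.05 level with at most a few
BH discoveries on 2000 all-null rows.

Known limitations: the scan-based aligner is quadratic in reference size
and intended for panels; the exact test enumerates all splits of a group
total (linear in total counts per row); dispersion moderation by the
cohort median assumes dispersion does not trend strongly with the mean
across the panel; and median-of-ratios normalization requires at least
one all-positive row and a mostly-null panel.
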