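---
title: "Cross-tissue commonality of cancer molecular subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue commonality of cancer molecular subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansubtype)
```

## The question

Molecular subtypes of different cancers are usually defined cohort by cohort,
each with its own platform, gene universe and nomenclature. Yet subtypes from
different tissues — a mesenchymal glioma, a basal-like breast tumor — can share
transcriptional programs. `pansubtype` quantifies that commonality directly
from expression data: it asks, for every pair of subtypes across a panel of
cohorts, how similar their samples look transcriptome-wide and pathway-wide,
which gene sets are dysregulated in each subtype, and how often the same
pathway recurs across tissues.

The pipeline has six stages:

1. **Preprocess.** Probe-level rows are collapsed to genes by averaging; every
   gene is median-centered within its cohort; cohorts are reduced to a common
   gene universe, dropping (with a recorded reason) any cohort that shares too
   few genes with the rest.
2. **Pathway profiles.** Every sample gets a single-sample GSEA (ssGSEA) score
   per gene set; positive scores mean the set's genes are coordinately
   upregulated in that sample.
3. **Correlation.** Spearman rank correlation between samples — of the full
   centered expression vector (the transcriptional profile) or of the ssGSEA
   score vector (the pathway profile) — is summarised per subtype pair by the
   median over all cross-subtype sample pairs.
4. **Phylogeny.** The subtype-by-subtype median correlation matrix is turned
   into the dissimilarity `1 - rho` and clustered with average linkage,
   yielding a subtype dendrogram exportable as Newick.
5. **GSEA.** Each subtype is contrasted one-vs-rest within its cohort with the
   weighted Kolmogorov–Smirnov enrichment statistic and a phenotype-permutation
   null; gene sets significant at FDR q < 0.25 in at least one subtype are
   retained and their recurrence across tissues tabulated.
6. **Pathway clustering.** The pooled pathway-profile matrix is clustered over
   samples (1 − Spearman, average linkage), split at the dendrogram root into
   two groups, and each subtype is tested for overrepresentation in a group by
   a 2×2 chi-squared test.

## Models and statistics

### ssGSEA score

For one sample, genes are ranked by decreasing expression (ties broken by gene
id, so scoring is deterministic). With in-set weights $w_i = |x_i|^\alpha$
(all 1 at $\alpha = 0$), the score is

$$ S = \sum_{j=1}^{N} \left[ P_{\mathrm{in}}(j) - P_{\mathrm{out}}(j) \right], $$

where $P_{\mathrm{in}}(j)$ is the cumulative normalized in-set weight down to
rank $j$ and $P_{\mathrm{out}}(j)$ the cumulative fraction of out-of-set
genes. `pathway_profile()` evaluates this through the equivalent closed form
$\sum_i w_i (N - p_i + 1)/W$ for the in-set term (an in-set gene at position
$p_i$ contributes to every later position), which makes profile construction
linear in set size after one sort per sample; `ssgsea_score()` keeps the
direct cumulative evaluation and the two are tested against each other and
against a brute-force oracle.

The weighting exponent defaults to $\alpha = 0.25$, the conventional ssGSEA
choice; it is exposed as `ssgsea.alpha` because published analyses do not
always state it. Scores are used raw — no rescaling across sets — and are
computed on the median-centered matrix by default (`ssgsea.input =
"centered"`), with `"raw"` available as a documented switch. Sets with fewer
than `min_set_size = 5` genes in a cohort's universe are dropped: a one- or
two-gene "set" is effectively a single noisy gene and would dominate
rank-correlations between pathway profiles.

### Subtype similarity and phylogeny

Between-sample similarity is Spearman rank correlation with average ranks for
ties (the conventional treatment; implemented as Pearson on rank vectors). The
subtype-level summary is the **median** over sample pairs: between subtypes of
different cohorts, all cross-cohort pairs; within a cohort, all within-cohort
pairs; on the diagonal, distinct within-subtype pairs with self-correlations
excluded (self-pairs are identically 1 and would inflate the diagonal).

The phylogeny uses $D = 1 - \mathrm{median}\ \rho$ (range $[0, 2]$, zero
diagonal) and UPGMA/average linkage. We ship our own small agglomerator rather
than calling `hclust` for one reason: tie-breaking. `hclust`'s merge order on
exactly tied distances depends on input order; ours always merges the
lexicographically smallest label pair, so trees are reproducible regardless of
cohort ordering. On tie-free matrices it agrees with `hclust` exactly (this is
a test). Average linkage on a proper dissimilarity is monotone, so merge
heights never decrease toward the root. Newick branch lengths are the
difference between the parent's and the node's merge height, with leaves at
height zero.

### One-vs-rest GSEA

The per-gene ranking metric follows the cohort's scale dialect: for
absolute-intensity cohorts, the signal-to-noise ratio
$(\mu_1 - \mu_0) / (\sigma_1 + \sigma_0)$ with each class sd floored at
$0.2\,|\mu|$ (and at $0.2$ when both the sd and mean are zero) — the standard
stabilization, without which constant genes produce infinite metrics; for
log-ratio cohorts, the difference of class means, since a ratio-scale sd sum
is not a meaningful denominator there. The enrichment score is the classic
weighted KS walk with hit weight $|m_i|^p$, $p = 1$ by default. When the
positive and negative extremes of the walk tie in magnitude the positive one
is reported — the tie must be broken somehow, and a fixed convention keeps the
C++ batch kernel, the reference R implementation and the test oracles in exact
agreement.

Significance comes from `n_perm = 1000` permutations of the one-vs-rest
phenotype labels (never gene-set permutation: phenotype permutation preserves
gene–gene correlation, and a single documented null keeps results
deterministic). Per set, NES is the ES divided by the mean magnitude of
same-sign null ES values; the nominal p is the same-sign tail fraction. The
FDR q is the ratio of tail fractions of the sign-separated null and observed
NES pools over all sets in the run, capped at 1 and made monotone by a running
minimum from the least extreme NES upward, so a more extreme NES never
receives a larger q. Subtypes with fewer than 3 samples are skipped, and below
7 a warning flags that the permutation null is coarse. The permutation kernel
is compiled (Rcpp): each permutation costs one $O(N \log N)$ ranking plus
$O(|S| \log |S|)$ per set.

Retention keeps gene sets with minimum q strictly below 0.25 in at least one
subtype. Recurrence classifies each retained set by the number of distinct
tissues among its significant (cohort, subtype) hits: one tissue =
tissue-specific, five or more = common, otherwise intermediate.

### Two-group split and enrichment

The pooled sets-by-samples score matrix is clustered over samples with
1 − Spearman and average linkage; the two children of the root merge define
groups K1/K2 (K1 contains the lexicographically smallest sample id, a purely
cosmetic but deterministic convention). Per subtype, the 2×2 table of subtype
membership against group membership is tested with Pearson's chi-squared
without continuity correction — reported borderline p-values in this kind of
analysis are consistent with the uncorrected test — and we test independence
against the overall group sizes (the natural margins) rather than a uniform
split. When any expected cell is below 5 the test switches to Fisher's exact
test and says so in the `method` column.

## The synthetic study conditions

Real inputs for this kind of analysis are public microarray cohorts, which
testing cannot depend on. The generator (`synthetic_design()`,
`generate_cohorts()`, `generate_gene_sets()`) emulates the statistical
structure the pipeline assumes:

* several cohorts over partially overlapping gene universes (a shared core
  plus cohort-private genes);
* 2–7 subtypes per cohort with fixed proportions;
* planted "programs": gene modules added at effect size `delta` (log2 units)
  to designated (cohort, subtype) slots — a program spanning cohorts plants a
  cross-tissue partnership, a single-member program a subtype-specific
  dysregulated set;
* Gaussian noise on the log scale, the standard working model for normalized
  microarray intensities;
* both scale dialects: absolute cohorts sit near a per-gene baseline
  $\mu_g \sim N(8, 1)$ (drawn once, shared across cohorts), log-ratio cohorts
  near 0.

The default preset is 3 cohorts × 60 samples × 2,000 genes (80% core), 3
subtypes each, four 50-gene programs at `delta = 1`, `noise_sd = 1` — sized so
the full pipeline runs in about a minute on one CPU while keeping the planted
effects at a realistic, not overwhelming, one log2 unit. Gene set collections
add 40 random 50-gene decoys drawn from the core (so every set is scoreable in
every cohort); decoy–module overlaps are recorded rather than forbidden,
because real pathway collections overlap too. `null_mode = TRUE` suppresses
all effects for type-I-error calibration.

What the generator does **not** emulate: probe-level noise, batch effects,
platform-specific intensity distributions, correlated background genes, and
unbalanced subtype prevalences. Passing tests therefore demonstrate that the
machinery recovers structure of the assumed form at the planted effect size —
not that any particular biological dataset will yield stable subtype
partnerships.

## Numerical and design choices

* **Gene matching is exact string equality**; identifier harmonization happens
  upstream and is out of scope. Missing expression values are rejected, not
  imputed — failing loudly beats silent bias.
* **Cohort exclusion** during gene intersection is greedy in input order
  against the running intersection (`min_common` default 5,000 genes, the
  scale of overlap between mainstream array platforms; synthetic
  configurations write a floor of a quarter of the smallest universe). Ties
  are not re-optimized: determinism over optimality.
* **Median-centering** applies to both scale dialects and is idempotent.
* **Metric ties** in ranking are broken by gene id; **distance ties** in
  clustering by smallest label pair; **walk-extreme ties** in the ES by
  preferring the positive deviation. All three are arbitrary conventions made
  explicit so that outputs are bit-reproducible.
* **Seeds** fan out by fixed offsets (per cohort: `seed + 100 * (i - 1)`; per
  subtype: `+ subtype index`; gene sets: `+ 1000`), so any stage can be
  re-run in isolation with the same stream.
* Whether published analyses of this design intersected genes globally or per
  cohort pair is typically unstated; we intersect globally for the phylogeny
  (one common universe keeps subtype entries comparable) and support pairwise
  maps through `cross_cohort_correlation()` for two-cohort views.
* For two-color ratio data we assume higher value = higher tumor expression;
  orientation metadata is rarely machine-readable.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on generated data: the
oracle comparisons use universes of ≤ 20 genes (1,000 Spearman pairs, all 254
subsets of 8 genes); null calibration uses 3 null cohorts × 200 decoy sets ×
1,000 permutations (~1,800 p-values); recovery and partnership checks use the
default preset over 3 and 5 seeds; the two-group check uses the two-group
preset (3 cohorts × 2 subtypes). These sizes were chosen so the whole battery
completes in a few minutes on one CPU while leaving the planted-signal margins
far from the decision thresholds.

## Known limitations

* The q-value construction is the GSEA-style pooled-tail estimate; with strong
  true positives in the collection it is mildly liberal for borderline sets
  (the pooled observed tail includes the true positives). The null-mode
  calibration test pins down its behavior when nothing is planted.
* Median correlations between subtypes are summaries over correlated sample
  pairs; no standard error is attached to them, matching their descriptive
  use in the phylogeny.
* `split_two()` always returns two groups; if the pathway profile has no
  two-block structure the split is still reported, and only the chi-squared
  results reveal that nothing is enriched.
* The pipeline assumes sample ids are unique across cohorts when profiles are
  pooled; the synthetic writer guarantees this, real configurations must.
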