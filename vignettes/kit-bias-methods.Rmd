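---
title: "Methods: quantifying DNA extraction kit effects on abundant and rare taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DNA extraction kit effects on abundant and rare taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitbias)
```

## The problem

When the same water sample is extracted with different commercial DNA
extraction kits and amplicon-sequenced, the resulting OTU tables differ —
and they differ most for the taxa least able to absorb noise: the rare
biosphere. `kitbias` implements an analysis pipeline for replicated
kit-comparison designs (several kits, each extracted in replicate from one
homogenized sample) that quantifies this differential effect: which part of
the community drives between-kit dissimilarity, how reproducible each kit's
replicates are along the abundance spectrum, and how much removing
low-abundance OTUs improves comparability between methods.

The canonical design the package targets is 5 kits x 3 replicates = 15
samples, each normalized to a common sequencing depth (41,744 sequences per
sample is a typical 16S depth; 121,146 a typical 18S depth).

## Abundance categories

Every OTU is classified from its relative abundances across all samples
analyzed together, using the classical abundant (>= 1%) and rare (< 0.01%)
biosphere cutoffs, into six exclusive categories: always abundant (AT),
conditionally abundant (CAT), conditionally rare and abundant (CRAT),
moderate (MT), conditionally rare (CRT) and always rare (RT).

One boundary convention is applied uniformly: *abundant* means relative
abundance `>= abundant_cutoff` and *rare* means strictly
`< rare_cutoff`, so an OTU sitting exactly at 0.01% is not rare.
Descriptions of these categories in the literature mix ">" and "between"
phrasings, which leaves boundary OTUs ambiguous; a single half-open
convention is the only way to make the six categories a partition, which is
what every downstream per-category analysis assumes. A zero count is
relative abundance 0 and therefore rare, so an OTU absent from any sample
can only be CRAT, CRT or RT. OTUs absent from *every* sample have no
defined relative abundance and are excluded with a warning.

Classification is pooled over all samples (all 15 in the canonical design)
rather than per kit, matching the exclusive-category definition; a per-kit
classification would let one OTU carry different labels in different kits
and break the roll-ups.

## Dissimilarities

Four metrics are provided, all in [0, 1]:

* **Bray-Curtis** `d = sum|x_i - y_i| / sum(x_i + y_i)` on per-sample
  relative abundances.
* **Jaccard** `1 - |A n B| / |A u B|` on presence/absence sets. The
  abundance-weighted Jaccard variant is deliberately not used: the
  presence/absence form is the standard complement to Bray-Curtis.
* **Unweighted UniFrac**: the fraction of tree branch length leading
  exclusively to tips present in one of the two samples.
* **Weighted UniFrac**: `sum_b l_b |p_bA - p_bB|`, with `p_bX` the fraction
  of sample X's sequences descending from branch b; normalized by
  `sum_b l_b (p_bA + p_bB)` by default so it shares the [0, 1] scale of
  the other three metrics.

Distances are computed on relative abundances, making them invariant to
residual depth differences. All metrics run on the same normalized table;
no additional per-metric rarefaction is applied. Tips present in the tree
but absent from the table are pruned; OTUs with nonzero counts missing from
the tree are an error (identifiers are matched by exact string equality).

For *category-subset* distances (per-category reproducibility, per-category
ANOSIM/PERMANOVA), Bray-Curtis is computed on the subset counts with the
denominator over the subset only — the question being asked is "how
variable is this slice of the community", not "how much does this slice
contribute to whole-community distance" (the latter is what SIMPER
answers). A pair of samples that both lack the category entirely has no
defined subset distance and is dropped from the averages.

## Permutation statistics

All permutation p-values use the `(hits + 1) / (n_permutations + 1)`
convention and accept a seed, so every reported p-value is reproducible.
Permutations are uniform random draws over group-label assignments.

* **ANOSIM**: midranks over all pairwise distances;
  `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
  Clarke's divisor, which maps complete separation to exactly R = 1.
* **PERMANOVA** (one-way): the squared-dissimilarity sums-of-squares
  partition with pseudo-F and R^2; 10,000 permutations by default
  (ANOSIM defaults to 999). A matrix of all-zero distances cannot be
  partitioned and is returned flagged degenerate instead of a p-value.
* **SIMPER**: the exact per-OTU decomposition of average between-group
  Bray-Curtis. It is defined pairwise; with more than two groups every
  group pair is reported, plus an aggregate defined as the unweighted mean
  over pairs (this aggregate is this package's convention, stated in the
  output). Supplying a category assignment adds per-category roll-ups
  (sums of member-OTU percentages).
* **IndVal**: specificity x fidelity x 100, maximized over groups;
  significance permutes whole samples, preserving within-sample OTU
  covariance; OTUs with IndVal > 50 and p < 0.05 are flagged valid.
  p-values are reported raw per OTU (no multiplicity correction), since the
  validity rule is a fixed threshold, not a family-wise claim.
* Classical tests (Kruskal-Wallis for alpha diversity across kits,
  Mann-Whitney U for two-group comparisons, one-way ANOVA for
  reproducibility across depths) delegate to the standard `stats`
  implementations.

## Kit assessment

**Reproducibility** of a kit is the mean pairwise dissimilarity among its
replicates (3 pairs for triplicates), with its standard error over those
pairs; lower is more consistent. Because "consistency" appears in both
orientations in the literature, `1 - dissimilarity` is emitted alongside
as `similarity`.

**Depth sensitivity** rarefies every sample to each depth in a grid
(without replacement, several independent draws), recomputes per-kit
reproducibility, and tests the depth effect per kit with one-way ANOVA.
Default grids follow the 16S convention (10,000-40,000) with the 18S grid
(10,000-100,000) available by argument.

**Levins niche breadth** `B_j = 1 / sum_i P_ij^2` uses `P_ij` = OTU j's
mean relative abundance in kit i, normalized across kits; B = 1 means
recovered by one kit only, B = N spread evenly over all N kits. Occurrence
counts the kits whose pooled replicates contain the OTU; pooling replicates
(union) is the standard convention for per-kit OTU inventories and is also
used for the Venn region counts.

**Filter sweep**: for each threshold t in (1, 5, 10, 50, 100, 500), OTUs
with dataset-wide total count <= t are removed (dataset-wide, consistent
with how singleton removal is usually applied), and within-kit dissimilarity,
between-kit dissimilarity and per-kit replicate overlap
(|intersection| / |union| of the replicates' OTU sets) are recomputed. Each
response is regressed on log10(t) by OLS — the predictor is not dictated by
any convention; log10 is chosen because the threshold grid is
logarithmic — and slope, intercept and R^2 are reported. A threshold that
removes every OTU is flagged and excluded from the regression.

## The synthetic community generator

Real kit-comparison sequencing data cannot ship with a package, so all
testing rests on `simulate_tables()`, which emulates the design the
analyses assume:

* Base relative abundances are lognormal (`meanlog = 0`, `sdlog = 3`), the
  standard heavy-tailed species-abundance model. With 2,000 OTUs at depth
  41,744 this puts the rare biosphere (RT + CRT) at roughly 80-90% of
  observed OTUs, the richness structure typical of plankton amplicon
  surveys.
* Each kit perturbs each OTU by a multiplicative bias `exp(N(0, sigma))`,
  with `sigma = 0.05` for OTUs in the abundant head and `sigma = 2.0` for
  the rare tail (85% of OTUs by base-abundance rank). No noise model for
  kit effects is established in the literature; multiplicative lognormal
  bias is this package's choice — it is the simplest mechanism that is
  depth-free, sign-symmetric on the log scale, and lets abundant and rare
  taxa be affected to different degrees. Tail membership is decided by
  base-abundance quantile, *not* by the downstream category labels, so
  parameter-recovery tests are not circular.
* Rare-tail OTUs additionally drop out of each replicate with probability
  0.1, emulating the chance absence of very rare taxa from individual
  extractions.
* Each replicate is a multinomial draw of exactly `depth` sequences from
  the biased, renormalized proportions — the post-normalization product of
  an amplicon pipeline.
* A random rooted bifurcating tree with exponential branch lengths is
  generated over the OTUs for the UniFrac metrics. The tree is independent
  of the abundance structure: there is no phylogenetic signal in the kit
  bias. This is the simplest null; analyses claiming phylogenetically
  clustered kit effects cannot be validated against this generator.

One structural consequence is worth stating plainly: under a single
lognormal profile with rare-tail bias of `sigma = 2`, OTUs near the 0.01%
cutoff are pushed across it in some kit, so the strictly-always-rare (RT)
category alone holds fewer OTUs than in real surveys, with the balance in
CRT. The generator reproduces the rare *biosphere's* dominance of richness
and of between-kit dissimilarity, not the exact RT/CRT split of any real
dataset.

What passing tests therefore show: the pipeline's statistics are correct
against independent oracles, its null behavior is calibrated, and it
recovers a rare-concentrated kit effect when one is present by
construction. What they do not show: anything about taxon-specific lysis
chemistry, contamination, primer bias, or chimeras — none of which are
simulated.

### Rarefaction semantics

`subsample_reads()` subsamples without replacement (multivariate
hypergeometric), matching the semantics of the `sub.sample` normalization
used in amplicon pipelines; a with-replacement variant is deliberately not
offered, since it changes the expected richness. Monte-Carlo rarefaction
curves are validated against the closed-form hypergeometric expectation
`E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))` (`expected_richness()`).

## Numerical choices and degenerate inputs

* Counts must be non-negative integers; real-valued tables are rejected
  naming the offending cell. Samples with zero total are rejected at load
  time (relative abundance undefined).
* Distance matrices are validated symmetric to 1e-12; SIMPER identities
  (contributions sum to the mean between-group dissimilarity, percentages
  to 100) hold to 1e-12 and are tested at that tolerance.
* ANOSIM ties get midranks — deterministic and standard.
* Empty category subsets are flagged and refused by downstream statistics
  (mirroring datasets in which a category, e.g. AT, simply does not occur).
* All stochastic stages take explicit seeds; `run_pipeline()` derives one
  sub-seed per stage from the master seed and logs them, so a rerun is
  byte-identical.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to keep a full run in the
low minutes while leaving every statistic in its calibrated regime:
oracle comparisons use 6-15 samples and 8-30 OTUs (with exhaustive
permutation enumeration up to 8 samples and 1,000 random tree/table cases
for UniFrac); the type-I calibration uses 200 null simulations of 500 OTUs
at depth 5,000; parameter recovery uses 20 seeds of the full study shape
(2,000 OTUs, 5 x 3 samples, depth 41,744).

## Known limitations

* One-way designs only: a single grouping factor (kit), no nested or
  multi-factor PERMANOVA, no dispersion test (a significant PERMANOVA can
  reflect dispersion as well as location differences — ANOSIM and the
  reproducibility profile partly disambiguate this).
* SIMPER inherits Bray-Curtis's blindness to joint absences.
* IndVal p-values are raw per-OTU permutation p-values.
* The generator's kit bias is OTU-independent given the tail split; real
  kits bias taxonomically coherent groups.
* No taxonomy handling: all roll-ups are by abundance category, not
  lineage.
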