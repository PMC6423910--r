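# kitbias

Quantifying how DNA extraction kits differentially affect abundant and
rare taxa in replicated amplicon surveys of plankton communities.

## The problem

Different DNA extraction kits recover measurably different microbial
communities from the *same* water sample, and the damage is not spread
evenly: low-abundance taxa — the rare biosphere that dominates OTU
richness — are affected far more than the abundant core. For anyone
comparing microbiome studies that used different extraction methods, the
practical questions are: *which* part of the community drives the
between-kit differences, *how reproducible* is each kit across replicate
extractions, and *how much* does removing low-abundance OTUs improve
comparability? `kitbias` answers these for the canonical replicated design
(several kits, each extracted in triplicate from one homogenized sample,
all samples rarefied to a common depth).

## What it computes

- **Six exclusive abundance categories** per OTU from its relative
  abundances across all samples, using the classical abundant (≥ 1%) and
  rare (< 0.01%) cutoffs: always abundant (AT), conditionally abundant
  (CAT), conditionally rare and abundant (CRAT), moderate (MT),
  conditionally rare (CRT), always rare (RT).
- **Alpha diversity** (observed OTUs, Shannon *H* = −Σ pᵢ ln pᵢ, Pielou
  evenness, Chao1 = S + F₁(F₁−1)/(2(F₂+1))) and Monte-Carlo rarefaction
  curves with a closed-form hypergeometric check.
- **Four dissimilarities**: Bray-Curtis, Jaccard (presence/absence),
  unweighted and (normalized) weighted UniFrac.
- **Permutation statistics**: ANOSIM (Clarke's
  R = (r̄_between − r̄_within)/(n(n−1)/4)), one-way PERMANOVA (pseudo-F,
  R², 10,000 permutations by default), SIMPER (the exact per-OTU
  decomposition of mean between-group Bray-Curtis, with per-category
  roll-ups), and indicator species analysis (IndVal = specificity ×
  fidelity × 100, valid when > 50 with p < 0.05). All p-values use the
  (hits + 1)/(N + 1) convention and are seed-reproducible.
- **Kit assessment**: per-kit replicate reproducibility (overall and per
  category), sequencing-depth sensitivity, Levins niche breadth
  B_j = 1/Σᵢ P²ᵢⱼ across kits, per-kit occurrence/Venn overlap, and a
  low-abundance-filter sweep (drop OTUs with total ≤ t for
  t = 1, 5, 10, 50, 100, 500; regress dissimilarity and replicate overlap
  on log₁₀ t).
- **A synthetic community generator** emulating the whole design
  (lognormal abundances, per-kit multiplicative bias concentrated on the
  rare tail, replicate dropout, multinomial sequencing, random phylogeny),
  so the entire pipeline is testable without sequencing data.

## Worked example

Simulate the canonical survey — 5 kits × 3 replicates, 2,000 OTUs,
41,744 sequences per sample, kit bias concentrated on the rare 85% of the
community — and run the core analyses:

```r
library(kitbias)
sim <- simulate_tables(simulation_config(seed = 11))
asg <- classify_otus(sim$table)
category_summary(asg, sim$table)
#>   category n_otus otu_percent n_sequences sequence_percent
#> 1       AT     10       0.633      358071           57.185
#> 2      CAT      2       0.127       12805            2.045
#> 3     CRAT      7       0.443       19918            3.181
#> 4       MT    179      11.329      156301           24.962
#> 5      CRT    728      46.076       76007           12.139
#> 6       RT    654      41.392        3058            0.488
```

Rare taxa (CRT + RT) are ~87% of OTUs but ~13% of sequences — the rare
biosphere dominates richness, not reads. The kits separate completely:

```r
dm <- bray_curtis(sim$table)
anosim(dm, sim$design, n_permutations = 999, seed = 12)
#> ANOSIM R = 1.0000, p = 0.001 (999 permutations)
permanova(dm, sim$design, n_permutations = 999, seed = 13)
#> pseudo-F = 26.9549, p = 0.001 (999 permutations)
#> R2 = 0.9151, pseudo-F = 26.9549
```

SIMPER attributes most of the between-kit dissimilarity to the rare
categories (CRT + RT ≈ 57%), and per-category reproducibility shows the
same asymmetry — for kit QD, replicate dissimilarity is 0.0098 for AT but
0.58 for RT:

```r
sp <- simper(sim$table, sim$design, asg)
sp$category_percent$aggregate
#>   category percent
#> 1       AT  13.480
#> ...
#> 5      CRT  54.837
#> 6       RT   2.385

rep <- reproducibility(dm, sim$design, asg, sim$table)
subset(rep, group == "QD" & category %in% c("AT", "MT", "RT"))
#>    group category n_pairs mean_dissimilarity      se similarity
#> 9     QD       AT       3            0.00981 0.00070      0.990
#> 24    QD       MT       3            0.05788 0.00165      0.942
#> 34    QD       RT       3            0.58154 0.01981      0.418
```

Filtering low-abundance OTUs steadily improves comparability — between-kit
dissimilarity falls from 0.168 to 0.111 and replicate overlap rises from
0.56 to 0.88 across the threshold grid:

```r
filter_sweep(sim$table, sim$design)$per_threshold
#>   threshold otus_retained within_mean between_mean mean_overlap
#> 1         1          1403      0.0541        0.168        0.556
#> ...
#> 6       500           120      0.0263        0.111        0.880
```

`run_pipeline(run_config(...))` chains every stage (normalization,
classification, alpha/beta diversity, the permutation statistics per
category, reproducibility, IndVal, niche breadth, Venn, filter sweep) and
writes TSV outputs plus a JSON run summary with all seeds.

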