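# clgkit

Reconstruction of ancestral chordate linkage groups (CLGs) and analysis of
paralogue retention after whole-genome duplication, for comparative
genomicists studying deep chromosome-scale conservation.

Chordate chromosomes preserve ancient gene linkage: genes that shared a
chromosome in the chordate ancestor tend to still share one in living
genomes, even though gene order within chromosomes has been thoroughly
scrambled.  Comparing an unduplicated outgroup genome with several
twice-duplicated vertebrate genomes, `clgkit`:

* derives **mutual-best-hit orthologue anchors** and detects synteny
  breakpoints along the outgroup with the windowed discontinuity statistic
  `D(i, i+1) = Σ_a (X^R_a(i+1) − X^L_a(i))²`, where `X^L`/`X^R` are
  left/right windowed means (W = 25 genes) of the indicator of the
  comparator chromosome carrying each anchor's orthologue;
* merges the resulting segments into **conserved linkage groups** lettered
  `A, B, C, …` by decreasing gene count;
* tests CLG–chromosome and CLG–window associations against a
  **hypergeometric null** (orthologues randomly distributed across the two
  genomes) with Bonferroni correction, at whole-chromosome scale and in
  50/100-gene sliding windows;
* **paints** duplicated genomes by local CLG ancestry in ≥20-gene windows,
  partitions chromosomes into homogeneous ancestry blocks, and links blocks
  across species into orthologous cells;
* computes per-cell **retention fractions** (CLG families retained on a
  chromosome ÷ CLG-defining outgroup genes, one family member counted per
  chromosome), assigns **α/β subgenome labels** within fusion-concordant
  pairs, and tests the retention asymmetry that distinguishes
  allotetraploidy from autotetraploidy: a bootstrap z-test against a
  uniform one-class null on (0, c) with c twice the overall retention mean,
  Hartigan's **dip test** of bimodality (exact statistic in C++, bootstrap
  p), cross-species retention correlations, and an exact permutation test
  of **fusion-pattern concordance** between subgenomes;
* ships a **genome-evolution simulator** (inversions, fusions with junction
  mixing, auto- then allotetraploidy with configurable subgenome retention,
  terminal lineages) that emits gene maps, similarity tables, orthogroups
  and full truth labels, so the whole pipeline is verifiable end to end.

## Worked example

Simulate the default study conditions (17 CLGs × ~300 genes; outgroup with
3 fusions; three ingroup species after 1R autotetraploidy, 6 stem fusions,
and 2R allotetraploidy with subgenome retentions 0.39/0.15) and run the
full analysis:

```r
library(clgkit)
sim <- simulate_genomes(simulation_config(seed = 20260921))
res <- run_pipeline(sim, analysis_config(seed = 20260921))

length(res$partition$clg_sizes)   # 17 linkage groups recovered
res$breakpoints                   # 3 consensus breakpoints, all 3 comparators
res$asymmetry
res$dip
```

Printed output of the asymmetry and dip tests on this run:

```
asymmetry test (uniform null, c = 0.506, m = 86 pairs)
  observed mean(high-low) = 0.2346, null 0.1687 +/- 0.0129
  z = 5.12, one-sided p = 1.52e-07
dip test: D = 0.1291, n = 212, bootstrap p = 9.999e-05 (10000 reps)
```

Reading this: across 86 α–β cell pairs the mean retention difference
(0.235) sits 5.1 standard deviations above the mean difference expected if
retention had a single class (uniform on 0–0.506), rejecting symmetric
loss — the signature of allotetraploidy.  The dip statistic rejects
unimodality of the pooled retention values (two classes near 0.37 and
0.14), and cross-species retention correlations of ~0.99 indicate the
losses predate the species splits.  Fusion patterns of the β subgenome
match the α subgenome exactly (6 of 6 pairs; exact permutation
p = 9.6 × 10⁻⁵), rejecting independent parallel fusions.

The same analysis as a stepwise narrative lives in `analysis/01_simulate.R`
… `analysis/06_retention.R`; each stage prints what it found and writes its
tables under `results/`.

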