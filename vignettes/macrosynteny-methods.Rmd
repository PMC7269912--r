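---
title: "Methods: ancestral linkage groups, genome duplications and retention asymmetry"
author: "clgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral linkage groups, genome duplications and retention asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chordate genomes retain, half a billion years after their divergence, a
striking form of conservation: genes that were linked on one ancestral
chromosome tend to remain linked — on the same chromosome, though in
scrambled order — in living descendants.  Comparing an unduplicated
outgroup genome (an amphioxus-like cephalochordate) with several bony
vertebrates lets one (i) partition the outgroup genome into ancestral
**conserved linkage groups** (CLGs), (ii) trace how those groups were
fused, mixed and duplicated along the vertebrate stem, and (iii) use the
pattern of duplicate gene *loss* to infer the mechanism of the two
vertebrate whole-genome duplications: symmetric loss after an
autotetraploidy (1R), asymmetric loss between the two parental subgenomes
(called α and β) after an allotetraploidy (2R).

`clgkit` implements this entire analysis as composable stages, plus a
genome-evolution simulator that generates multi-species gene maps with
known truth labels, so that every stage can be validated quantitatively
without any external data.

# Coordinates, anchors and the discontinuity statistic

All statistics operate on **gene ordinals**: the 0-based rank of a gene
along its chromosome.  Base-pair coordinates are carried for display only,
and gene orientation is ignored throughout — synteny is used in its
classical sense of physical linkage without regard to order.

Orthologue anchors are **mutual best hits** (MBH): a pair is accepted only
when each gene is the other's *unique* top-scoring match in reciprocal
similarity searches.  A tie for the top score disqualifies the gene; MBH is
deliberately a conservative orthology criterion.  Genes of the outgroup
with an orthologue in at least one comparator form the anchor set, the
coordinate system of the linkage-group inference.

For a comparator species, each anchor *i* carries an indicator vector
$x_a(i)$ that is 1 for the comparator chromosome $a$ holding its orthologue
and 0 elsewhere.  With windowed averages
$X^L_a(i)$ (the mean over the $W$ anchors ending at $i$) and $X^R_a(i)$
(over the $W$ anchors starting at $i$), the discontinuity between adjacent
anchors is

$$D(i, i+1) = \sum_a \left( X^R_a(i+1) - X^L_a(i) \right)^2 ,$$

which lies in $[0, 2]$: 0 when both windows have the same composition, 2
only for a complete switch from one comparator chromosome to another.
Windows are truncated near chromosome ends (the mean is taken over the
available anchors), and junctions with fewer than $\lceil W/2 \rceil$
anchors on either side are not eligible as breakpoints, which suppresses
edge artefacts of the truncation.

**Parameters.** `W = 25` genes is the default window; it trades boundary
localisation (±a few genes) against noise in the windowed means.  The peak
threshold `peak_threshold = 0.5` accepts local maxima of $D$ corresponding
to at least a 50% composition switch; `min_separation = W` keeps called
peaks apart.  Breakpoints are called per comparator and a consensus
boundary requires support from at least two comparators within $W/2$
anchors; the consensus junction is the $D$-weighted median of the
supporting calls.

A note on the magnitude of $D$ against duplicated comparators: when the
comparator genome has itself undergone two rounds of duplication, the
orthologues of one linkage group are spread over up to four chromosomes
with weights $w$, so a *complete* ancestry switch yields
$D \approx \sum_X w^2 + \sum_Y w^2$, about 0.5–0.8 under the study's
retention rates rather than the idealised 2.  The 0.5 default therefore
sits near the lower edge of the signal; background fluctuation peaks stay
below ≈0.3 at $W = 25$, and we verified on simulations that 0.5 recovers
junctions with sensitivity ≈0.97 and precision ≈1.0, while 0.3 trades
precision (≈0.65) for little sensitivity.  The default stays at 0.5.

# Merging segments into linkage groups

Consensus breakpoints cut the outgroup chromosomes into segments; segments
whose mean indicator vectors are closely aligned — cosine similarity at or
above `merge_threshold` in a majority of comparators — are merged
(single linkage) into one unit, and units are lettered A, B, C, … by
decreasing anchor count (ties broken by smallest chromosome identifier).

The merge threshold defaults to **0.75**, not 0.5, for a geometric reason:
two segments of the *same* linkage group have cosine ≈ 1, while two
*different* linkage groups that share exactly one pre-2R fusion have mean
indicator vectors of the form $(a, b, a, b)$ and $(a, b, c, d)$ on their
four descendant chromosomes, whose cosine is exactly 0.5 in expectation
regardless of the retention rates.  A threshold at 0.5 sits on that
degeneracy and merges about half of such fusion partners; 0.75 is the
midpoint between the two regimes.

A user-supplied `manual_merges` list lets curated groupings (for example,
treating several outgroup chromosomes as one unit for specific analyses) be
reproduced explicitly; no automatic rule is claimed for such cases.

# Enrichment testing

Under the null that orthologues are randomly distributed across the two
genomes, the number shared between a linkage group (K anchors of the
N-anchor universe) and a chromosome or window (n anchors) is
hypergeometric; the test is one-sided (enrichment only) and the universe is
the per-species-pair MBH anchor set, not the full gene complement.
Bonferroni correction uses m = (#linkage groups × #chromosomes) at
chromosome scale, and m = (#windows actually tested × #linkage groups),
pooled per species pair, for the window scans — pooling is the more
conservative reading.  Windows slide over anchored-gene ordinals with step
`window/2` (25 for the 50-gene scan), so every window holds exactly
`window` anchors; empty windows cannot arise and the last window is pinned
to the chromosome end.  Two-tier reporting mirrors the standard annotation:
**strong** = 50-gene window $p < 0.01$; **weak** = 50-gene $p < 0.05$,
100-gene $p < 0.01$ or whole-chromosome $p < 0.05$.

The hypergeometric tail itself is delegated to R's stable distribution
routines (log-space); the test suite checks it against exhaustive
enumeration for every parameter combination with $N \le 25$.

# Painting and orthologous cells

Ingroup genes inherit the linkage-group ancestry of their gene family
(majority over the family's outgroup members).  Chromosomes are painted in
non-overlapping windows of at least 20 genes (per-window ancestry
fractions; genes without an assigned family contribute no mass, so
fractions sum to ≤ 1), and partitioned into homogeneous blocks by running
the same discontinuity statistic on the ancestry-label sequence, accepting
the largest remaining peak iteratively subject to a 20-gene exclusion zone.
A boundary between two adjacent blocks with the same dominant ancestry is
treated as a mixing artefact and dropped — a genuine second copy of a group
on the same chromosome is separated by other ancestry and survives this
rule (such same-chromosome copies receive sub-labels a/b).

Blocks are linked across species into orthologous **cells** by shared
gene-family content, greedily in decreasing shared-count order (ties broken
deterministically by species then chromosome; a block tied between two
cells at a positive count is flagged ambiguous and excluded from retention
pairing).  The fusion pattern of a cell is the set of other dominant
linkage groups co-resident on its chromosome, taken as the majority pattern
across its species.

# Retention and the duplication-mechanism tests

The **retention fraction** of a cell is the number of linkage-group
families with a member inside the cell's segments divided by the number of
group-defining genes in the outgroup.  Families are counted once per
chromosome (for sub-labelled cells, once per segment), so tandem
duplications never inflate retention, while unlinked duplicates — the
signature of genome-scale events — do count, and the total retention of a
group across one species can exceed 1.  Defining-gene denominators count
*every* outgroup gene inside the group's segments (segments are extended to
chromosome ends), not only anchored genes: a family that lost all of its
duplicated copies still helps define its ancestral group.

**α/β assignment.** Cells of one group are paired by fusion concordance
(equal co-resident sets — the two subgenomes inherit identical fusion
patterns from the inter-duplication stem).  Within a pair the cell with the
higher mean retention across species is α.  When a pattern group holds four
cells (no fusion anywhere), cells are ordered by retention and split
half/half; the pairing (not the labelling) is then arbitrary and flagged.
Cells without a counterpart are labelled α-without-β and excluded from the
asymmetry test, which only makes the test conservative.  Copy labels 1/2
carry no retention ordering; the pair with the larger gene total is 1.
A chromosome must be wholly α or wholly β; disagreements are flagged
rather than resolved.

**Asymmetry test.** The observed statistic is the mean within-pair
difference (high − low).  The null draws m pairs iid from a uniform
distribution on $(0, c)$ with $c$ twice the overall retention mean (a
single retention class), orders each pair, and computes the same statistic;
its mean and standard deviation are estimated by bootstrap (default $10^6$
replicates, seedable and chunked) and reported alongside the closed forms
$E = c/3$ and $\mathrm{sd} = c/\sqrt{18m}$.  The z-score and one-sided
normal p follow.  A normal-family null (moments from the data) is
available; on bimodal data it sits even farther from the observations, so
the uniform null is the conservative choice.  The overall retention mean
behind $c$ is computed over all non-missing cells; `c_upper` can be passed
explicitly, which calibration studies should do so that the simulated null
and the test share one scale.

**Dip test.** Bimodality of the pooled α/β retention values is assessed
with the dip statistic — the sup-norm distance between the empirical CDF
and the closest unimodal CDF (convex, then concave, with an atom allowed at
the mode).  The implementation minimises, over all mode placements, the
band half-width that admits a convex minorant on the left and a concave
majorant on the right (with a junction feasibility term), computed exactly
in C++ via incremental hulls; an independent quadratic-time chord-
enumeration reference validates it to $10^{-12}$ in the test suite.  The
p-value is a bootstrap against uniform samples of equal size (default
$10^4$ replicates), the standard calibration for this statistic;
`dip_null_table()` lets one null table be shared across tests of equal n.

**Fusion concordance.** To reject independent identical fusions in the two
subgenomes, the statistic is the number of fused β pairs identical (as
group pairs) to an α pair; the null is a uniformly random perfect matching
of the β segments, enumerated exactly up to $10^6$ matchings
($(2k-1)!!$ for $2k$ segments) and sampled beyond.  Chromosomes carrying
three or more groups do not define a pairwise matching and are excluded
from this test.

# The simulator and what it emulates

`simulate_genomes()` implements the inferred scenario forward in time: an
ancestral genome of 17 linkage groups (gene counts Poisson with mean 300);
an outgroup lineage with within-chromosome inversions (order scrambling)
and 3 fusions with sharp junctions; an ingroup stem with autotetraploidy
(per-copy retention 1 by default, so that the configured 2R rates equal
end-state cell retentions; 1R-era loss can be switched on), 6 stem fusions
with two junction-spanning inversions each, then allotetraploidy with
subgenome retentions 0.39 (α) and 0.15 (β) applied on the stem — so
descendant species share most losses, which is what makes cross-species
retention correlations high — followed by 3% per-terminal loss and local
rearrangement in three terminal lineages.

Design choices that matter:

* **Loss is per family per chromosome-copy** (Bernoulli), so realized
  retention fractions directly estimate the configured rates.
* **`min_retained_copies` defaults to 0.** A family may lose every
  duplicated copy — the outgroup still defines it, and the denominators
  count it.  Conditioning every family on survival would inflate per-copy
  retention by 1/P(any survivor) ≈ 1.37 at the default rates, divorcing
  realized retentions from the configured ones.  The constraint remains
  available, and with all-zero rates and `min_retained = 1` it realises the
  exactly-one-survivor-of-four experiment whose expected per-segment
  retention is 25%.
* **Post-fusion inversions are span-bounded** (default 40 genes):
  accumulated local rearrangements scramble gene order and mix fusion
  junctions without dissolving macro-scale ancestry blocks.  Unbounded
  inversions would turn every fused chromosome into an alternating mosaic,
  which is not what comparative painting of real genomes shows.  The
  quantitative mixing rate is a free parameter; two junction-spanning
  inversions per fusion leave sharp-but-mixing-adjacent boundaries.
* **Stem fusions use distinct group pairs by default**
  (`stem_fusions_distinct`), so every linkage group keeps an unfused copy —
  the identifiability precondition the real system satisfies (every
  ancestral group survives unfused in at least one descendant).  If both
  copies of two groups fuse pairwise, no synteny-based method can separate
  them.
* **Similarity scores**: each ingroup gene carries one divergence drawn
  from |N(0, 5)| plus a tiny uniform jitter (making top scores almost
  surely unique), and true-family pairs score 100 − divergence over a
  uniform 10–40 background; mutual best hits are therefore correct by
  construction at default noise, and noise can be raised for stress tests.

What the simulator does **not** emulate: sequence evolution (scores are
schematic), gene-order hotspots, tandem-duplication families (retention
counting is exercised by dedicated fixtures instead), unequal chromosome
loss, homoeologous recombination after duplication, and lineage-specific
extra duplications (an optional question the simulator leaves off by
default).  Passing the validation suite therefore demonstrates correctness
of the *inference machinery* under the stated generative model, not
robustness to every feature of real genomes.

# Numerical and reproducibility choices

All randomness flows from integer seeds; stochastic operations snapshot and
restore the caller's RNG state, so a run is a pure function of (inputs,
configuration, seed) and writing the same analysis twice produces
byte-identical files — the run manifest records the configuration, its
digest and file checksums, and deliberately no timestamps.  Bootstrap
resampling is chunked to bound memory at about $2 \times 10^6$ doubles per
chunk.  Unplaced genes are excluded from all counts and the manifest says
so.  Ties are broken deterministically everywhere (lexicographic gene ids,
smallest chromosome identifier, species order).

Problem sizes used by the validation suite: 17 groups × ~300 genes ×
4 species for end-to-end runs; 20 replicate simulations for breakpoint
recovery and group-count checks; 500 replicates at $10^4$ bootstrap
draws for null calibration of the asymmetry z; $10^6$ draws for the
closed-form comparison; $10^5$ families for the symmetric-loss
expectation; exhaustive hypergeometric enumeration to N = 25.

# Known limitations

* Cells whose pairing is ambiguous (no fusion pattern and four equivalent
  copies) are paired arbitrarily-but-deterministically; the α/β *labels*
  remain correct whenever the two subgenome retention distributions are
  well separated, but the pair structure itself carries no evidence.
* The asymmetry z-test against the uniform one-class null is conservative
  when the data are narrowly symmetric (observed differences far below the
  null mean give large negative z, not a calibrated 5% rejection rate),
  and with ~30 pairs at the study's rates its power at the 0.01 level is
  about 0.85–0.9, not 1.
* Block boundaries are estimated from discretised ancestry labels; a few
  genes at block edges can be mis-assigned, which biases per-cell retention
  slightly downward (≈1–3% relative at default mixing).
* Consensus boundaries require two supporting comparators; with only one
  comparator the consensus reduces to that comparator's calls.
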