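#!/usr/bin/env Rscript
# Stage 3: synteny breakpoints and ancestral linkage groups.
#
# Computes the windowed synteny-discontinuity statistic D along each
# outgroup chromosome against every ingroup comparator (W = 25 genes),
# calls consensus breakpoints (local peaks of D supported by >= 2
# comparators), cuts chromosomes into segments, and merges segments with
# closely aligned synteny profiles into conserved linkage groups lettered
# by decreasing gene count.

library(clgkit)

ds <- read_dataset("results/dataset")
mbh <- lapply(names(ds$similarity), function(sp)
  mutual_best_hits(ds$similarity[[sp]]$fwd, ds$similarity[[sp]]$rev))
names(mbh) <- names(ds$similarity)
anchors <- build_anchor_set(ds$gene_maps$outgroup, mbh, ds$gene_maps)

bp <- consensus_breakpoints(anchors, W = 25, threshold = 0.5)
cat("consensus synteny breakpoints:\n")
print(bp[, c("chromosome", "junction", "D", "support")])
if (!is.null(ds$truth)) {
  cat("true junctions for comparison:\n")
  print(ds$truth$outgroup_junctions[, c("chromosome", "junction")])
}

segments <- segment_chromosomes(anchors, bp)
partition <- merge_segments(anchors, segments)
cat(sprintf("%d segments merged into %d linkage groups:\n",
            nrow(segments), length(partition$clg_sizes)))
print(partition$clg_sizes)

wt <- clgkit:::write_tsv
wt(bp, "results/breakpoints.tsv")
wt(partition$segments, "results/clg_segments.tsv")
wt(partition$assignment, "results/clg_assignment.tsv")
for (sp in names(mbh))
  wt(oxford_dotplot_data(anchors, sp, partition),
     sprintf("results/dotplot_%s.tsv", sp))
cat("wrote results/breakpoints.tsv, clg_segments.tsv, clg_assignment.tsv\n")
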