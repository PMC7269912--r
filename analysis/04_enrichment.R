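#!/usr/bin/env Rscript
# Stage 4: hypergeometric enrichment of orthologue sharing.
#
# Tests every (linkage group, ingroup chromosome) association against the
# hypergeometric null in which orthologues are randomly distributed across
# the two genomes, at whole-chromosome scale and in sliding windows of 50
# and 100 anchored genes, all Bonferroni-corrected; summarises each cell
# into the two-tier strong/weak annotation.

library(clgkit)

ds <- read_dataset("results/dataset")
mbh <- lapply(names(ds$similarity), function(sp)
  mutual_best_hits(ds$similarity[[sp]]$fwd, ds$similarity[[sp]]$rev))
names(mbh) <- names(ds$similarity)
anchors <- build_anchor_set(ds$gene_maps$outgroup, mbh, ds$gene_maps)
partition <- merge_segments(anchors,
                            segment_chromosomes(anchors,
                                                consensus_breakpoints(anchors)))

all_res <- list(); all_tiers <- list()
for (sp in names(mbh)) {
  e50 <- window_enrichment(partition, anchors, sp, 50L)
  e100 <- window_enrichment(partition, anchors, sp, 100L)
  ech <- chromosome_enrichment(partition, anchors, sp)
  tiers <- significance_tier(e50, e100, ech)
  cat(sprintf("%-6s: %3d strong and %3d weak associations (m=%d window tests)\n",
              sp, sum(tiers$tier == "strong"), sum(tiers$tier == "weak"),
              e50$m[1L]))
  all_res[[sp]] <- rbind(e50, e100, ech)
  all_tiers[[sp]] <- tiers
}

wt <- clgkit:::write_tsv
wt(do.call(rbind, all_res), "results/enrichment.tsv")
wt(do.call(rbind, all_tiers), "results/enrichment_tiers.tsv")
cat("wrote results/enrichment.tsv, enrichment_tiers.tsv\n")
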