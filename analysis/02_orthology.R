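#!/usr/bin/env Rscript
# Stage 2: mutual-best-hit orthology and anchor construction.
#
# Derives reciprocal-best-hit orthologue pairs between the outgroup and each
# ingroup species from the similarity tables, then assembles the anchor set:
# outgroup genes with an orthologue in at least one ingroup, ordered along
# the outgroup genome.  These anchors are the coordinate system of the
# linkage-group inference.

library(clgkit)

ds <- read_dataset("results/dataset")
mbh <- lapply(names(ds$similarity), function(sp)
  mutual_best_hits(ds$similarity[[sp]]$fwd, ds$similarity[[sp]]$rev))
names(mbh) <- names(ds$similarity)
for (sp in names(mbh))
  cat(sprintf("outgroup vs %-6s: %5d mutual best hits\n", sp,
              nrow(mbh[[sp]]$pairs)))

anchors <- build_anchor_set(ds$gene_maps$outgroup, mbh, ds$gene_maps)
cat(sprintf("anchor set: %d of %d outgroup genes have >= 1 orthologue\n",
            nrow(anchors$anchors), nrow(ds$gene_maps$outgroup$genes)))

dir.create("results", showWarnings = FALSE)
write_tsv <- clgkit:::write_tsv
write_tsv(anchors$anchors, "results/anchors.tsv")
for (sp in names(mbh))
  write_tsv(mbh[[sp]]$pairs, sprintf("results/mbh_outgroup_%s.tsv", sp))
cat("wrote results/anchors.tsv\n")
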