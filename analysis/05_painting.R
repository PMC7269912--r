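#!/usr/bin/env Rscript
# Stage 5: ancestry painting of the duplicated genomes.
#
# Maps every ingroup gene to its linkage-group ancestry through the gene
# families, paints chromosomes in windows of >= 20 genes (per-window
# ancestry fractions), partitions each chromosome into homogeneous ancestry
# blocks by iterative largest-peak splitting, and links blocks across
# species into orthologous cells (linkage group x copy).

library(clgkit)

ds <- read_dataset("results/dataset")
mbh <- lapply(names(ds$similarity), function(sp)
  mutual_best_hits(ds$similarity[[sp]]$fwd, ds$similarity[[sp]]$rev))
names(mbh) <- names(ds$similarity)
anchors <- build_anchor_set(ds$gene_maps$outgroup, mbh, ds$gene_maps)
partition <- merge_segments(anchors,
                            segment_chromosomes(anchors,
                                                consensus_breakpoints(anchors)))

ingroups <- names(mbh)
ancestries <- lapply(ds$gene_maps[ingroups], clg_gene_ancestry,
                     orthogroups = ds$orthogroups, partition = partition,
                     outgroup = "outgroup")
painting <- lapply(ancestries, paint_windows)
blocks <- lapply(ancestries, partition_blocks)
for (sp in ingroups)
  cat(sprintf("%-6s: %3d ancestry blocks on %2d chromosomes, mean purity %.3f\n",
              sp, nrow(blocks[[sp]]),
              length(unique(blocks[[sp]]$chromosome)),
              mean(blocks[[sp]]$purity, na.rm = TRUE)))

cells <- assign_copies(blocks, ancestries)
cat(sprintf("%d orthologous cells over %d linkage groups\n",
            length(unique(paste(cells$clg, cells$cell))),
            length(unique(cells$clg))))

wt <- clgkit:::write_tsv
wt(do.call(rbind, Map(function(sp, p) cbind(species = sp, p),
                      names(painting), painting)), "results/painting.tsv")
wt(do.call(rbind, Map(function(sp, b) cbind(species = sp, b),
                      names(blocks), blocks)), "results/blocks.tsv")
wt(cells, "results/cells.tsv")
cat("wrote results/painting.tsv, blocks.tsv, cells.tsv\n")
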