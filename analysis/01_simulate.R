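#!/usr/bin/env Rscript
# Stage 1: generate the study-condition dataset.
#
# Simulates an unduplicated outgroup genome descended from 17 ancestral
# linkage groups (3 fusions with sharp junctions, within-group order
# scrambling) and three post-2R ingroup genomes produced by autotetraploidy,
# six stem fusions with junction mixing, and allotetraploidy with asymmetric
# subgenome retention (alpha 0.39, beta 0.15), plus light terminal loss and
# rearrangement.  Writes gene maps, similarity tables, orthogroups and truth
# labels under results/dataset/.

library(clgkit)

seed <- 20260921L
cfg <- simulation_config(seed = seed)
sim <- simulate_genomes(cfg)
write_dataset(sim, "results/dataset")

cat("simulated", length(sim$gene_maps), "gene maps (seed", seed, "):\n")
for (sp in names(sim$gene_maps)) {
  gm <- sim$gene_maps[[sp]]
  cat(sprintf("  %-9s %5d genes on %2d chromosomes\n", sp, nrow(gm$genes),
              length(unique(gm$genes$chromosome))))
}
cat("true outgroup fusion junctions:\n")
print(sim$truth$outgroup_junctions[, c("chromosome", "junction")])
cat("stem fusions (shared by both subgenomes):",
    nrow(sim$truth$stem_fusions), "\n")
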