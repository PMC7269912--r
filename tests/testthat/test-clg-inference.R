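# build a synteny_indicator directly from a sequence of comparator
# chromosome labels along one outgroup chromosome
label_indicator <- function(labels, chromosome = "c1") {
  chroms <- sort(unique(labels))
  structure(list(comparator = "cmp", chromosomes = chroms,
                 genes = data.frame(outgroup_gene = paste0("g", seq_along(labels)),
                                    chromosome = chromosome,
                                    ordinal = seq_along(labels) - 1L,
                                    col = match(labels, chroms),
                                    stringsAsFactors = FALSE)),
            class = "synteny_indicator")
}

test_that("indicator profile has one unit row per anchored orthologue", {
  out <- toy_map("out", list(c1 = paste0("o", 1:5)))
  tmap <- toy_map("t", list(chrA = paste0("t", 1:4)))
  mbh <- list(t = toy_orthology("out", "t", paste0("o", 1:4), paste0("t", 1:4)))
  anc <- build_anchor_set(out, mbh, list(t = tmap))
  ind <- indicator_profile(anc, "t")
  expect_equal(nrow(ind$genes), 4L)          # o5 has no orthologue: no row
  expect_equal(ind$chromosomes, "chrA")
  expect_true(all(ind$genes$col == 1L))
  expect_error(indicator_profile(anc, "nope"), "not among")
})

test_that("discontinuity is 0 on homogeneous chromosomes and 2 at a full switch", {
  prof <- discontinuity(label_indicator(rep("A", 80)), W = 25)
  expect_true(all(prof$D == 0))
  prof2 <- discontinuity(label_indicator(rep(c("A", "B"), each = 80)), W = 25)
  at <- prof2$D[prof2$junction == 80]
  expect_equal(at, 2)
  expect_true(all(prof2$D >= 0 & prof2$D <= 2))
  expect_equal(max(prof2$D), 2)
})

test_that("windowed means use truncated windows near chromosome ends", {
  # W=2 over A,A,B,B: hand evaluation gives D = 0.5, 2, 0.5
  prof <- discontinuity(label_indicator(c("A", "A", "B", "B")), W = 2)
  expect_equal(prof$D, c(0.5, 2, 0.5))
})

test_that("D is invariant to comparator relabeling and order reversal", {
  set.seed(8)
  labs <- sample(c("A", "B", "C"), 120, TRUE, prob = c(.5, .3, .2))
  d1 <- discontinuity(label_indicator(labs), W = 10)$D
  relab <- c(A = "Z", B = "Q", C = "M")[labs]
  d2 <- discontinuity(label_indicator(unname(relab)), W = 10)$D
  expect_equal(d1, d2)
  d3 <- discontinuity(label_indicator(rev(labs)), W = 10)$D
  expect_equal(d3, rev(d1))
})

test_that("breakpoints are peaks over threshold with minimum separation", {
  labs <- c(rep("A", 40), rep("B", 40), rep("C", 40))
  prof <- discontinuity(label_indicator(labs), W = 25)
  bp <- detect_breakpoints(prof, threshold = 0.5, min_separation = 25)
  expect_equal(bp$junction, c(40L, 80L))
  # flat profile below threshold: nothing
  prof0 <- discontinuity(label_indicator(rep("A", 60)), W = 25)
  expect_equal(nrow(detect_breakpoints(prof0, 0.5, 25)), 0L)
  # min_separation suppresses the weaker of two close peaks
  labs2 <- c(rep("A", 30), rep("B", 10), rep("C", 40))
  prof2 <- discontinuity(label_indicator(labs2), W = 8)
  bp2 <- detect_breakpoints(prof2, threshold = 0.5, min_separation = 25)
  expect_equal(nrow(bp2), 1L)
})

test_that("junctions too close to chromosome ends are not eligible", {
  labs <- c(rep("A", 5), rep("B", 100))
  prof <- discontinuity(label_indicator(labs), W = 25)
  expect_false(any(prof$eligible[prof$junction < 13]))
  bp <- detect_breakpoints(prof, 0.5, 25)
  expect_false(any(bp$junction == 5))
})

test_that("simulated fusion junctions are recovered within a few genes", {
  hits <- 0; total <- 0; found <- 0
  for (s in 1:3) {
    sim <- simulate_genomes(simulation_config(seed = 100 + s))
    res_mbh <- lapply(names(sim$similarity), function(sp)
      mutual_best_hits(sim$similarity[[sp]]$fwd, sim$similarity[[sp]]$rev))
    names(res_mbh) <- names(sim$similarity)
    anc <- build_anchor_set(sim$gene_maps$outgroup, res_mbh, sim$gene_maps)
    bp <- consensus_breakpoints(anc)
    truth <- sim$truth$outgroup_junctions
    total <- total + nrow(truth)
    found <- found + nrow(bp)
    for (i in seq_len(nrow(truth))) {
      cand <- bp[bp$chromosome == truth$chromosome[i], , drop = FALSE]
      if (nrow(cand) &&
          min(bp_distance(cand$ordinal_left, cand$ordinal_right,
                          truth$junction[i])) <= 5)
        hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)   # sensitivity
  expect_lte(found, total + 1)    # essentially no false positives
})

test_that("segments merge back into the configured linkage groups", {
  for (s in 1:2) {
    sim <- simulate_genomes(simulation_config(seed = 200 + s))
    mbh <- lapply(names(sim$similarity), function(sp)
      mutual_best_hits(sim$similarity[[sp]]$fwd, sim$similarity[[sp]]$rev))
    names(mbh) <- names(sim$similarity)
    anc <- build_anchor_set(sim$gene_maps$outgroup, mbh, sim$gene_maps)
    part <- merge_segments(anc, segment_chromosomes(anc,
                                                    consensus_breakpoints(anc)))
    expect_equal(length(part$clg_sizes), sim$config$n_clgs)
    # letters are assigned in decreasing order of gene count
    expect_equal(names(part$clg_sizes), make_clg_letters(sim$config$n_clgs))
    expect_true(all(diff(unname(part$clg_sizes)) <= 0))
    # every anchored gene is in exactly one CLG
    expect_equal(nrow(part$assignment), nrow(anc$anchors))
    # truth agreement: each inferred CLG maps to one true linkage group
    tg <- sim$truth$genes
    true_clg <- tg$clg[match(part$assignment$gene_id,
                             tg$gene_id[tg$species == "outgroup"])]
    purity <- tapply(true_clg, part$assignment$clg, function(x)
      max(table(x)) / length(x))
    expect_gte(min(purity), 0.95)
  }
})

test_that("segment profiles control merging", {
  out <- toy_map("out", list(c1 = paste0("a", 1:60), c2 = paste0("b", 1:60)))
  # both outgroup chromosomes map to the same comparator chromosome: merge
  tmap <- toy_map("t", list(X = paste0("t", 1:120)))
  mbh <- list(t = toy_orthology("out", "t", c(paste0("a", 1:60), paste0("b", 1:60)),
                                paste0("t", 1:120)))
  anc <- build_anchor_set(out, mbh, list(t = tmap))
  segs <- segment_chromosomes(anc, consensus_breakpoints(anc))
  part <- merge_segments(anc, segs)
  expect_equal(length(part$clg_sizes), 1L)
  # disjoint comparator chromosomes: never merged (cosine 0)
  tmap2 <- toy_map("t", list(X = paste0("t", 1:60), Y = paste0("u", 1:60)))
  mbh2 <- list(t = toy_orthology("out", "t", c(paste0("a", 1:60), paste0("b", 1:60)),
                                 c(paste0("t", 1:60), paste0("u", 1:60))))
  anc2 <- build_anchor_set(out, mbh2, list(t = tmap2))
  part2 <- merge_segments(anc2, segment_chromosomes(anc2,
                                                    consensus_breakpoints(anc2)))
  expect_equal(length(part2$clg_sizes), 2L)
})

test_that("oxford dot plot data covers every shared anchor", {
  sim <- simulate_genomes(tiny_config(seed = 5))
  mbh <- list(sp1 = mutual_best_hits(sim$similarity$sp1$fwd,
                                     sim$similarity$sp1$rev))
  anc <- build_anchor_set(sim$gene_maps$outgroup, mbh, sim$gene_maps)
  dp <- oxford_dotplot_data(anc, "sp1")
  expect_equal(nrow(dp), sum(!is.na(anc$anchors$gene.sp1)))
  expect_setequal(dp$target_index, seq_len(nrow(dp)))
})
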