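test_that("null evolution yields identical maps and full MBH recovery", {
  cfg <- simulation_config(n_clgs = 1, genes_per_clg = 10,
                           outgroup_fusions = 0, outgroup_inversions = 0,
                           stem_inversions = 0, stem_fusions = 0,
                           wgd1_retention = 1,
                           wgd2_retention = c(alpha = 1, beta = 1),
                           divergence_inversions = 0, terminal_loss = 0,
                           terminal_inversions = 0,
                           ingroup_species = c("s1", "s2"),
                           background_hits = 0, seed = 1)
  sim <- simulate_genomes(cfg)
  n_out <- nrow(sim$gene_maps$outgroup$genes)
  # both ingroups carry identical gene content (modulo species prefix)
  strip <- function(gm) sub("^s[12]_", "", gm$genes$gene_id)
  expect_setequal(strip(sim$gene_maps$s1), strip(sim$gene_maps$s2))
  mbh <- mutual_best_hits(sim$similarity$s1$fwd, sim$similarity$s1$rev)
  expect_equal(nrow(mbh$pairs), n_out)
})

test_that("scrambling preserves gene content and zero inversions are identity", {
  ids <- paste0("g", 1:50)
  expect_identical(scramble(ids, 0), ids)
  set.seed(5)
  s <- scramble(ids, 20)
  expect_setequal(s, ids)
  expect_false(identical(s, ids))
  s2 <- scramble(ids, 15, span = 5)
  expect_setequal(s2, ids)
})

test_that("fusion without mixing keeps a sharp junction", {
  f <- fuse_and_mix(paste0("a", 1:30), paste0("b", 1:30), 0)
  expect_equal(f$junction, 30L)
  expect_equal(f$order, c(paste0("a", 1:30), paste0("b", 1:30)))
  set.seed(6)
  fm <- fuse_and_mix(paste0("a", 1:100), paste0("b", 1:100),
                     mixing_inversions = 10, span = 60)
  expect_setequal(fm$order, c(paste0("a", 1:100), paste0("b", 1:100)))
  near <- fm$order[81:120]  # 20 genes each side of the junction
  expect_true(any(grepl("^a", near)) && any(grepl("^b", near)))
})

test_that("whole-genome duplication doubles content at full retention", {
  g <- data.frame(gene_id = paste0("g", 1:40), chromosome = "c1",
                  pos = 1:40, family_id = paste0("F", 1:40),
                  stringsAsFactors = FALSE)
  set.seed(7)
  d <- apply_wgd(g, "auto", 1, label_field = "copy", labels = c("1", "2"))
  expect_equal(nrow(d), 80L)
  expect_equal(sort(unique(d$copy)), c("1", "2"))
  expect_true(all(table(d$family_id) == 2L))
  # boundary rates: allo (1, 0) without a minimum empties the beta subgenome
  db <- apply_wgd(g, "allo", c(1, 0), label_field = "subgenome",
                  labels = c("alpha", "beta"), min_retained = 0)
  expect_equal(sum(db$subgenome == "beta"), 0L)
  expect_equal(sum(db$subgenome == "alpha"), 40L)
  # with min_retained = 1, forced survivors are exactly the all-lost families
  dc <- apply_wgd(g, "allo", c(0, 0), label_field = "subgenome",
                  labels = c("alpha", "beta"), min_retained = 1)
  expect_equal(nrow(dc), 40L)
  expect_true(all(table(dc$family_id) == 1L))
})

test_that("per-copy retention is binomial about the configured rate", {
  g <- data.frame(gene_id = paste0("g", 1:2000), chromosome = "c1",
                  pos = 1:2000, family_id = paste0("F", 1:2000),
                  stringsAsFactors = FALSE)
  set.seed(8)
  d <- apply_wgd(g, "auto", 0.5, label_field = "copy", labels = c("1", "2"))
  r1 <- sum(d$copy == "1") / 2000
  r2 <- sum(d$copy == "2") / 2000
  expect_equal(r1, 0.5, tolerance = 4 * sqrt(0.25 / 2000))
  expect_equal(r2, 0.5, tolerance = 4 * sqrt(0.25 / 2000))
})

test_that("family count never grows and truth matches the emitted maps", {
  sim <- simulate_genomes(simulation_config(seed = 9, n_clgs = 5,
                                            genes_per_clg = 80,
                                            outgroup_fusions = 1,
                                            stem_fusions = 2))
  n_anc <- sum(sim$truth$genes$species == "outgroup")
  for (sp in sim$config$ingroup_species) {
    fams <- unique(sim$orthogroups$family_id[sim$orthogroups$species == sp])
    expect_lte(length(fams), n_anc)
    tg <- sim$truth$genes[sim$truth$genes$species == sp, ]
    gm <- sim$gene_maps[[sp]]$genes
    expect_setequal(tg$gene_id, gm$gene_id)
    m <- match(gm$gene_id, tg$gene_id)
    expect_equal(tg$chromosome[m], gm$chromosome)
  }
})

test_that("same seed reproduces the dataset byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 10, n_clgs = 3, genes_per_clg = 60,
                           outgroup_fusions = 1, stem_fusions = 1)
  write_dataset(simulate_genomes(cfg), d1)
  write_dataset(simulate_genomes(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("stem fusions are shared by both subgenomes", {
  sim <- simulate_genomes(simulation_config(seed = 12))
  sf <- sim$truth$stem_fusions
  expect_gt(nrow(sf), 0L)
  tg <- sim$truth$genes[sim$truth$genes$species == "gar", ]
  # a fused stem chromosome appears with both -alpha and -beta suffixes
  # unless one side lost all genes
  fused <- paste0(sf$chromosome[1L], c("-alpha", "-beta"))
  expect_true(any(tg$chromosome %in% fused))
})

test_that("impossible fusion demands are rejected", {
  expect_error(simulate_genomes(simulation_config(n_clgs = 2,
                                                  outgroup_fusions = 3,
                                                  seed = 1)),
               "more fusions")
})
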