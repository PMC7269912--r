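test_that("ordinals follow bp order with lexicographic tie-break", {
  gm <- gene_map("sp", data.frame(gene_id = c("g1", "g2", "g3"),
                                  chromosome = "chr1",
                                  bp_start = c(100, 500, 200)))
  expect_equal(gm$genes$ordinal[match(c("g1", "g2", "g3"), gm$genes$gene_id)],
               c(0L, 2L, 1L))
  tie <- gene_map("sp", data.frame(gene_id = c("b", "a"), chromosome = "chr1",
                                   bp_start = c(100, 100)))
  expect_equal(tie$genes$gene_id, c("a", "b"))
})

test_that("ordinals are a bijection onto 0..n-1 per chromosome", {
  set.seed(4)
  gm <- gene_map("sp", data.frame(
    gene_id = paste0("g", 1:50),
    chromosome = sample(c("c1", "c2", "c3"), 50, TRUE),
    bp_start = sample(1e6, 50)))
  for (ch in unique(gm$genes$chromosome)) {
    o <- sort(gm$genes$ordinal[gm$genes$chromosome == ch])
    expect_equal(o, seq_along(o) - 1L)
  }
})

test_that("duplicate gene ids are a hard error naming the gene", {
  expect_error(gene_map("sp", data.frame(gene_id = c("g1", "g1"),
                                         chromosome = "c1",
                                         bp_start = c(1, 2))),
               "g1")
})

test_that("gene map files round-trip through the TSV dialect", {
  gm <- toy_map("sp", list(c1 = paste0("a", 1:7), c2 = paste0("b", 1:4)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gene_map(gm, tf)
  back <- read_gene_map(tf, "tsv")
  expect_equal(back$species, "sp")
  expect_equal(back$genes[c("gene_id", "chromosome", "ordinal")],
               gm$genes[c("gene_id", "chromosome", "ordinal")])
})

test_that("empty gene map file yields an empty map with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tf)
  expect_warning(gm <- read_gene_map(tf, "tsv", species = "sp"), "empty")
  expect_equal(nrow(gm$genes), 0L)
})

test_that("BED maps are read and missing coordinates rejected", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t200\tgA", "c1\t50\t90\tgB"), tf)
  gm <- read_gene_map(tf, "bed", species = "sp")
  expect_equal(gm$genes$gene_id, c("gB", "gA"))
  writeLines(c("c1\t100\t200"), tf)
  expect_error(read_gene_map(tf, "bed"), "4 columns")
})

test_that("similarity reader handles tabular dialects and bad scores", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", "a\tb\t50", "a\tb\t70", "c\td\t10"), tf)
  st <- read_similarity(tf, "s1", "s2")
  expect_equal(nrow(st$hits), 2L)
  expect_equal(st$hits$score[st$hits$query == "a"], 70)  # max-collapse
  # 12-column alignment output: columns 1, 2, 12
  row12 <- paste(c("q", "s", "90.1", "100", "1", "0", "1", "100", "1",
                   "100", "1e-30", "123.4"), collapse = "\t")
  writeLines(row12, tf)
  st <- read_similarity(tf, "s1", "s2")
  expect_equal(st$hits$score, 123.4)
  writeLines("a\tb\tnotanumber", tf)
  expect_error(read_similarity(tf, "s1", "s2"), "line 1")
})

test_that("result writing is deterministic and records the configuration", {
  cfg <- analysis_config(seed = 5L)
  tabs <- list(scores = data.frame(x = 1:3, y = c("a", "b", "c")),
               empty = data.frame(p = numeric(), q = character()))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(tabs, d1, cfg)
  write_results(tabs, d2, cfg)
  for (f in c("scores.tsv", "empty.tsv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # header-only TSV for the empty table
  expect_equal(readLines(file.path(d1, "empty.tsv")), "p\tq")
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 5L)
  expect_true(nzchar(man$config_digest))
  # config drift is visible in the digest
  write_results(tabs, d2, analysis_config(seed = 6L))
  man2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_false(identical(man$config_digest, man2$config_digest))
})

test_that("YAML configuration round-trips into analysis_config", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("W: 31", "peak_threshold: 0.4", "seed: 9"), tf)
  cfg <- read_config(tf)
  expect_equal(cfg$W, 31L)
  expect_equal(cfg$peak_threshold, 0.4)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$paint_min_window, 20L)  # untouched default
})

test_that("config invariants are enforced", {
  expect_error(analysis_config(W = 1))
  expect_error(analysis_config(peak_threshold = 0))
  expect_error(analysis_config(peak_threshold = 2.5))
})

test_that("GFF3 gene features are accepted as a gene map dialect", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t100\t900\t.\t+\t.\tID=gA",
    "c1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=gA.t1;Parent=gA",
    "c1\tsrc\tgene\t1000\t1800\t.\t-\t.\tID=gB",
    "c2\tsrc\tgene\t5\t80\t.\t+\t.\tID=gC"), tf)
  gm <- read_gene_map(tf, "gff3", species = "sp")
  expect_equal(nrow(gm$genes), 3L)  # mRNA feature ignored
  expect_equal(gm$genes$gene_id[gm$genes$chromosome == "c1"], c("gA", "gB"))
  expect_equal(gm$genes$ordinal[gm$genes$gene_id == "gC"], 0L)
})
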