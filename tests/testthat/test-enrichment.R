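test_that("upper-tail hypergeometric matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(20, 5, 5, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(10, 5, 5, 3), 126 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(10, 5, 5, 0), 1)
  for (N in c(6, 9, 12)) for (K in 0:N) for (n in 0:N)
    for (k in 0:min(K, n))
      expect_equal(hypergeom_upper_tail(N, K, n, k), hyper_enum(N, K, n, k),
                   tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(10, 11, 5, 1), "invalid")
  expect_error(hypergeom_upper_tail(10, 5, 5, 6), "invalid")
})

test_that("p decreases as the overlap grows", {
  p <- vapply(0:8, function(k) hypergeom_upper_tail(40, 10, 8, k), numeric(1))
  expect_true(all(diff(p) < 0))
})

# a 1:1 two-species scenario with known CLG-chromosome correspondence
one_to_one_setup <- function(n_clg = 4, genes = 80) {
  ids <- paste0("g", seq_len(n_clg * genes))
  out <- toy_map("out", split(paste0("o", ids),
                              rep(paste0("c", 1:n_clg), each = genes)))
  tg <- toy_map("t", split(paste0("t", ids),
                           rep(paste0("X", 1:n_clg), each = genes)))
  mbh <- list(t = toy_orthology("out", "t", paste0("o", ids), paste0("t", ids)))
  anc <- build_anchor_set(out, mbh, list(t = tg))
  part <- merge_segments(anc, segment_chromosomes(anc,
                                                  consensus_breakpoints(anc)))
  list(anchors = anc, partition = part)
}

test_that("true chromosome associations are significant, others not", {
  su <- one_to_one_setup()
  res <- chromosome_enrichment(su$partition, su$anchors, "t")
  expect_equal(nrow(res), 16L)
  expect_equal(res$m[1L], 16L)
  hit <- res$n_overlap == res$n_clg   # the true cells
  expect_true(all(res$p_bonferroni[hit] < 0.01))
  expect_true(all(res$p_bonferroni[!hit] > 0.9))
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  expect_true(all(res$p_bonferroni <= pmin(1, res$p_raw * res$m[1L]) + 1e-15))
})

test_that("degenerate universe returns p 1", {
  su <- one_to_one_setup(n_clg = 1, genes = 30)
  res <- chromosome_enrichment(su$partition, su$anchors, "t")
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_raw, 1)
})

test_that("a single window over a whole chromosome equals the chromosome test", {
  su <- one_to_one_setup(n_clg = 2, genes = 50)
  rw <- window_enrichment(su$partition, su$anchors, "t", window_size = 50,
                          step = 50)
  rc <- chromosome_enrichment(su$partition, su$anchors, "t")
  key <- function(d) paste(d$clg, d$chromosome)
  rw <- rw[order(key(rw)), ]
  rc <- rc[order(key(rc)), ]
  expect_equal(nrow(rw), nrow(rc))
  expect_equal(rw$p_raw, rc$p_raw, tolerance = 1e-12)
})

test_that("hypergeometric p-values are calibrated under random assignment", {
  # shuffle orthologue placement and check the raw p distribution
  set.seed(21)
  n_clg <- 4; genes <- 60
  ids <- paste0("g", seq_len(n_clg * genes))
  out <- toy_map("out", split(paste0("o", ids),
                              rep(paste0("c", 1:n_clg), each = genes)))
  hits <- 0; tests <- 0; alpha <- 0.1
  for (rep in 1:40) {
    tg <- toy_map("t", split(paste0("t", sample(ids)),
                             rep(paste0("X", 1:n_clg), each = genes)))
    mbh <- list(t = toy_orthology("out", "t", paste0("o", ids),
                                  paste0("t", ids)))
    anc <- build_anchor_set(out, mbh, list(t = tg))
    part <- structure(list(
      assignment = data.frame(gene_id = paste0("o", ids),
                              chromosome = rep(paste0("c", 1:n_clg),
                                               each = genes),
                              ordinal = rep(0:(genes - 1), n_clg),
                              clg = rep(LETTERS[1:n_clg], each = genes)),
      segments = NULL,
      clg_sizes = stats::setNames(rep(genes, n_clg), LETTERS[1:n_clg])),
      class = "clg_partition")
    res <- chromosome_enrichment(part, anc, "t")
    hits <- hits + sum(res$p_raw < alpha)
    tests <- tests + nrow(res)
  }
  # discrete conservatism allowed: observed rate within binomial error of
  # alpha and not anticonservative
  rate <- hits / tests
  expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / tests))
  expect_gt(rate, 0.02)
})

test_that("significance tiers follow the two-tier annotation rule", {
  mk <- function(p, scale) data.frame(clg = "A", target = "t",
                                      chromosome = "X", scale = scale,
                                      p_bonferroni = p)
  tier <- function(p50, p100, pch)
    significance_tier(mk(p50, "window50"), mk(p100, "window100"),
                      mk(pch, "chromosome"))$tier
  expect_equal(tier(0.005, 1, 1), "strong")
  expect_equal(tier(0.2, 1, 0.03), "weak")
  expect_equal(tier(0.03, 1, 1), "weak")
  expect_equal(tier(1, 0.005, 1), "weak")
  expect_equal(tier(1, 1, 1), "none")
})
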