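# build a labelled retention table directly for unit tests
toy_retention <- function(vals) {
  do.call(rbind, lapply(names(vals), function(cl) {
    v <- vals[[cl]]
    data.frame(clg = cl, cell = seq_along(v), sublabel = "",
               species = "sp", chromosome = paste0(cl, seq_along(v)),
               fusion_pattern = "", ambiguous = FALSE,
               numerator = round(v * 100), denominator = 100, retention = v,
               stringsAsFactors = FALSE)
  }))
}

test_that("retention is family count over defining genes, tandem-safe", {
  # outgroup: one chromosome, 5 families; target: one chromosome carrying
  # 3 of them, one as a tandem pair
  out <- toy_map("out", list(c1 = paste0("o", 1:5)))
  tmap <- toy_map("t", list(X = c("t1", "t1b", "t2", "t3")))
  og <- orthogroup_table(data.frame(
    family_id = c(paste0("F", 1:5), "F1", "F1", "F2", "F3"),
    species = c(rep("out", 5), rep("t", 4)),
    gene_id = c(paste0("o", 1:5), "t1", "t1b", "t2", "t3")))
  mbh <- list(t = toy_orthology("out", "t", paste0("o", 1:3),
                                c("t1", "t2", "t3")))
  anc <- build_anchor_set(out, mbh, list(t = tmap))
  part <- merge_segments(anc, segment_chromosomes(anc,
                                                  consensus_breakpoints(anc)))
  ancs <- list(t = clg_gene_ancestry(tmap, og, part, "out"))
  cells <- data.frame(clg = "A", cell = 1L, sublabel = "", species = "t",
                      chromosome = "X", block = 1L, start_ordinal = 0L,
                      end_ordinal = 4L, n_genes = 4L, clgs = "A",
                      fusion_pattern = "", ambiguous = FALSE)
  ret <- retention_fractions(cells, part, og, ancs, "out",
                             outgroup_map = out)
  # 3 families retained out of 5 defining genes; the tandem pair counts once
  expect_equal(ret$numerator, 3L)
  expect_equal(ret$denominator, 5L)
  expect_equal(ret$retention, 0.6)
})

test_that("alpha/beta assignment orders within fusion-concordant pairs", {
  ret <- toy_retention(list(A = c(0.40, 0.14)))
  ret$fusion_pattern <- "B"
  out <- assign_alpha_beta(ret)
  expect_equal(out$subgenome[out$retention == 0.40], "alpha")
  expect_equal(out$subgenome[out$retention == 0.14], "beta")
  expect_equal(unique(out$pair_id), out$pair_id[1L])
  # a cell with no candidate partner is alpha-without-beta
  solo <- assign_alpha_beta(toy_retention(list(B = 0.3)))
  expect_equal(solo$subgenome, "alpha_no_beta")
})

test_that("four same-pattern cells split into two high-low pairs", {
  ret <- toy_retention(list(A = c(0.42, 0.38, 0.16, 0.13)))
  out <- assign_alpha_beta(ret)
  expect_setequal(out$subgenome[out$retention > 0.25], "alpha")
  expect_setequal(out$subgenome[out$retention < 0.25], "beta")
  expect_true(all(out$pair_arbitrary))
  expect_equal(length(unique(out$pair_id)), 2L)
  # copy 1 is the pair with the larger gene total
  p1 <- out$pair_id[out$copy == 1L][1L]
  tot <- tapply(out$numerator, out$pair_id, sum)
  expect_equal(names(which.max(tot)), p1)
})

test_that("chromosome-sharing cells must agree in subgenome", {
  ret <- rbind(toy_retention(list(A = c(0.4, 0.1), B = c(0.35, 0.12))))
  # put A's alpha and B's beta on one chromosome: conflict
  ret$chromosome <- c("x1", "x2", "x3", "x1")
  out <- assign_alpha_beta(ret)
  expect_true(any(out$chromosome_conflict[out$chromosome == "x1"]))
})

test_that("asymmetry bootstrap matches the uniform closed forms", {
  pairs <- data.frame(alpha = rep(0.39, 24), beta = rep(0.15, 24))
  res <- asymmetry_test(pairs, reps = 2e5, seed = 42)
  expect_equal(res$c_upper, 0.54, tolerance = 1e-12)
  expect_equal(res$null_mean, res$null_mean_exact, tolerance = 0.02)
  expect_equal(res$null_sd * sqrt(res$m) * sqrt(18), res$c_upper,
               tolerance = 0.03)
  # frozen analytic z for these inputs: (0.24 - c/3) / (c / sqrt(18 m))
  z_exact <- (0.24 - 0.54 / 3) / (0.54 / sqrt(18 * 24))
  expect_equal(res$z, z_exact, tolerance = 0.05)
  expect_equal(z_exact, 2.309, tolerance = 1e-3)
})

test_that("asymmetry test is deterministic and sided correctly", {
  pairs <- data.frame(alpha = runif(10, 0.2, 0.4), beta = runif(10, 0.1, 0.2))
  r1 <- asymmetry_test(pairs, reps = 1e4, seed = 7)
  r2 <- asymmetry_test(pairs, reps = 1e4, seed = 7)
  expect_identical(r1$z, r2$z)
  expect_identical(r1$p, r2$p)
  # identical pair members: observed difference 0, below the null mean
  same <- data.frame(alpha = rep(0.3, 12), beta = rep(0.3, 12))
  rs <- asymmetry_test(same, reps = 1e4, seed = 1)
  expect_lt(rs$z, 0)
  expect_gt(rs$p, 0.5)
  expect_error(asymmetry_test(same[1, ]), "at least 2")
})

test_that("normal-family null is available and farther from the data", {
  pairs <- data.frame(alpha = rep(0.39, 24), beta = rep(0.15, 24))
  ru <- asymmetry_test(pairs, null = "uniform", reps = 5e4, seed = 2)
  rn <- asymmetry_test(pairs, null = "normal", reps = 5e4, seed = 2)
  expect_true(is.finite(rn$z))
  expect_equal(rn$null_family, "normal")
  expect_gt(rn$z, ru$z)  # the uniform null is the conservative choice here
})

test_that("retention correlations behave at the extremes", {
  two <- rbind(toy_retention(list(A = c(0.4, 0.2), B = c(0.3, 0.1))),
               toy_retention(list(A = c(0.4, 0.2), B = c(0.3, 0.1))))
  two$species <- rep(c("s1", "s2"), each = 4)
  expect_equal(retention_correlation(two, "s1", "s2")$r, 1)
  anti <- two
  anti$retention[anti$species == "s2"] <- 0.5 - anti$retention[anti$species == "s2"]
  expect_lt(retention_correlation(anti, "s1", "s2")$r, 0)
  flat <- two
  flat$retention[flat$species == "s2"] <- 0.25
  expect_true(retention_correlation(flat, "s1", "s2")$degenerate)
  expect_error(retention_correlation(two[c(1, 5), ], "s1", "s2"), "3 shared")
})

test_that("fusion concordance p-values match exact enumeration", {
  # 4 beta segments, alpha pairs {A+B, C+D}, beta identical: 1 of 3 matchings
  res <- fusion_concordance_test(list(c("A", "B"), c("C", "D")),
                                 list(c("A", "B"), c("C", "D")))
  expect_equal(res$statistic, 2L)
  expect_equal(res$n_matchings, 3)
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  # beta pairs disjoint from alpha pairs: p = 1
  res2 <- fusion_concordance_test(list(c("A", "B"), c("C", "D")),
                                  list(c("A", "C"), c("B", "D")))
  expect_equal(res2$statistic, 0L)
  expect_equal(res2$p, 1)
  # 7 identical fusion pairs (14 segments): exact p = 1/13!!
  ap <- lapply(seq(1, 13, 2), function(i) LETTERS[c(i, i + 1)])
  res3 <- fusion_concordance_test(ap, ap)
  expect_true(res3$exact)
  expect_equal(res3$n_matchings, 135135)
  expect_equal(res3$p, 1 / 135135, tolerance = 1e-12)
  expect_lt(res3$p, 1e-5)
})
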