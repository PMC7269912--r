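# small in-code fixtures shared across tests

# a gene map from a compact spec: list(chr = c(gene ids in order))
toy_map <- function(species, chroms) {
  rows <- do.call(rbind, lapply(names(chroms), function(ch)
    data.frame(gene_id = chroms[[ch]], chromosome = ch,
               bp_start = 1000 * seq_along(chroms[[ch]]),
               stringsAsFactors = FALSE)))
  gene_map(species, rows)
}

# identity 1:1 orthology between two equally named gene sets with a prefix
toy_orthology <- function(sp_a, sp_b, genes_a, genes_b) {
  structure(list(species = c(sp_a, sp_b),
                 pairs = data.frame(gene_a = genes_a, gene_b = genes_b,
                                    stringsAsFactors = FALSE)),
            class = "orthology_table")
}

# similarity table from a matrix-like data.frame of (query, subject, score)
toy_similarity <- function(from, to, ...) {
  rows <- list(...)
  similarity_table(from, to,
                   data.frame(query = vapply(rows, `[[`, "", 1L),
                              subject = vapply(rows, `[[`, "", 2L),
                              score = as.numeric(vapply(rows, `[[`, "", 3L)),
                              stringsAsFactors = FALSE))
}

# tiny two-species simulation without duplication, for 1:1 checks
tiny_config <- function(seed = 1L, n_clgs = 3L, genes = 60, ...) {
  simulation_config(n_clgs = n_clgs, genes_per_clg = genes,
                    outgroup_fusions = 0L, outgroup_inversions = 5L,
                    stem_inversions = 5L, stem_fusions = 0L,
                    wgd1_retention = 1, wgd2_retention = c(alpha = 1, beta = 1),
                    divergence_inversions = 0L, terminal_loss = 0,
                    terminal_inversions = 2L, ingroup_species = c("sp1", "sp2"),
                    background_hits = 50L, seed = seed, ...)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail: sum the
# probability of every draw composition by binomial coefficients
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# distance from a detected breakpoint interval to a true junction ordinal
bp_distance <- function(ordinal_left, ordinal_right, truth) {
  pmax(0, pmax((ordinal_left + 1) - truth, truth - ordinal_right))
}
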