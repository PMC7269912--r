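#' Upper-tail hypergeometric probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability that a draw of
#' n anchors from a universe of N containing K marked anchors contains at
#' least k marked ones.  This is the null for orthologue sharing between
#' chromosomes (or windows) when orthologous genes are randomly distributed
#' across the two genomes.  Computed in log space via the stable distribution
#' routines.
#'
#' @param N Universe size. @param K Marked anchors. @param n Draw size.
#' @param k Observed overlap.
#' @return The p-value P[X >= k].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (length(N) != 1L || N < 0 || K < 0 || n < 0 || K > N || n > N)
    stop("invalid hypergeometric parameters: need 0 <= K, n <= N")
  if (k < 0 || k > min(K, n))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Whole-chromosome CLG enrichment
#'
#' One upper-tail hypergeometric test per (CLG, target chromosome), with a
#' Bonferroni correction for m = (#CLGs x #target chromosomes) tests.  The
#' universe N is the number of anchors shared by the species pair (genes with
#' an orthologue in this target), following the use of the mutual-best-hit
#' set rather than full gene counts.
#'
#' @param partition A \code{\link{merge_segments}} result.
#' @param anchors The \code{\link{anchor_set}}.
#' @param target Target species name.
#' @param levels Significance levels for flag columns.
#' @return data.frame with one row per test: \code{clg}, \code{target},
#'   \code{chromosome}, \code{scale} ("chromosome"), \code{window_start},
#'   \code{window_end} (NA), \code{n_universe}, \code{n_clg}, \code{n_window},
#'   \code{n_overlap}, \code{p_raw}, \code{m}, \code{p_bonferroni} and one
#'   logical column \code{sig_<level>} per level.
#' @export
chromosome_enrichment <- function(partition, anchors, target,
                                  levels = c(0.01, 0.05)) {
  a <- anchors$anchors
  clg <- partition$assignment$clg[match(a$outgroup_gene,
                                        partition$assignment$gene_id)]
  tc <- a[[paste0("chrom.", target)]]
  keep <- !is.na(tc) & !is.na(clg)
  clg <- clg[keep]; tc <- tc[keep]
  N <- sum(keep)
  clgs <- names(partition$clg_sizes)
  chroms <- sort(unique(tc))
  ov <- table(factor(clg, levels = clgs), factor(tc, levels = chroms))
  Kv <- rowSums(ov); nv <- colSums(ov)
  m <- length(clgs) * length(chroms)
  res <- expand.grid(clg = clgs, chromosome = chroms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$target <- target
  res$scale <- "chromosome"
  res$window_start <- NA_integer_; res$window_end <- NA_integer_
  res$n_universe <- N
  res$n_clg <- Kv[res$clg]
  res$n_window <- nv[res$chromosome]
  res$n_overlap <- ov[cbind(res$clg, res$chromosome)]
  res$p_raw <- mapply(hypergeom_upper_tail, N, res$n_clg, res$n_window,
                      res$n_overlap)
  res$m <- m
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  for (al in levels) res[[sprintf("sig_%g", al)]] <- res$p_bonferroni < al
  res[, c("clg", "target", "chromosome", "scale", "window_start", "window_end",
          "n_universe", "n_clg", "n_window", "n_overlap", "p_raw", "m",
          "p_bonferroni", sprintf("sig_%g", levels))]
}

#' Sliding-window CLG enrichment
#'
#' The same hypergeometric test applied to sliding windows of anchored genes
#' along each target chromosome.  Windows slide in anchored-gene ordinals
#' with the given step; the Bonferroni denominator m counts the windows
#' actually tested across all chromosomes of the species pair times the
#' number of CLGs (pooled per species pair).
#'
#' @inheritParams chromosome_enrichment
#' @param window_size Window size in anchored genes (e.g. 50 or 100).
#' @param step Step between window starts (default window_size / 2).
#' @return data.frame as in \code{\link{chromosome_enrichment}} with
#'   \code{scale} = "window<size>" and per-window rows.
#' @export
window_enrichment <- function(partition, anchors, target, window_size = 50L,
                              step = max(1L, window_size %/% 2L),
                              levels = c(0.01, 0.05)) {
  stopifnot(window_size >= 2)
  a <- anchors$anchors
  clg <- partition$assignment$clg[match(a$outgroup_gene,
                                        partition$assignment$gene_id)]
  tc <- a[[paste0("chrom.", target)]]
  to <- a[[paste0("ord.", target)]]
  keep <- !is.na(tc) & !is.na(clg)
  clg <- clg[keep]; tc <- tc[keep]; to <- to[keep]
  N <- sum(keep)
  clgs <- names(partition$clg_sizes)
  Kv <- table(factor(clg, levels = clgs))
  rows <- list()
  for (chr in sort(unique(tc))) {
    sel <- tc == chr
    o <- order(to[sel])
    cl <- clg[sel][o]
    ords <- to[sel][o]
    n <- length(cl)
    w <- min(window_size, n)
    starts <- unique(c(seq(1L, max(1L, n - w + 1L), by = step),
                       max(1L, n - w + 1L)))
    for (s in starts) {
      e <- s + w - 1L
      cnt <- table(factor(cl[s:e], levels = clgs))
      rows[[length(rows) + 1L]] <-
        data.frame(clg = clgs, chromosome = chr,
                   window_start = ords[s], window_end = ords[e] + 1L,
                   n_window = w, n_overlap = as.integer(cnt),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$target <- target
  res$scale <- sprintf("window%d", window_size)
  res$n_universe <- N
  res$n_clg <- as.integer(Kv[res$clg])
  m <- nrow(res)   # windows tested x CLGs, pooled per species pair
  res$p_raw <- mapply(hypergeom_upper_tail, N, res$n_clg, res$n_window,
                      res$n_overlap)
  res$m <- m
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  for (al in levels) res[[sprintf("sig_%g", al)]] <- res$p_bonferroni < al
  res[, c("clg", "target", "chromosome", "scale", "window_start", "window_end",
          "n_universe", "n_clg", "n_window", "n_overlap", "p_raw", "m",
          "p_bonferroni", sprintf("sig_%g", levels))]
}

# best (minimum) corrected p per (clg, chromosome) for one scale
summarize_enrichment <- function(res) {
  key <- paste(res$clg, res$chromosome, sep = "\r")
  best <- tapply(res$p_bonferroni, key, min)
  first <- res[!duplicated(key), c("clg", "target", "chromosome", "scale")]
  first$p_bonferroni <- as.numeric(best[paste(first$clg, first$chromosome,
                                              sep = "\r")])
  rownames(first) <- NULL
  first
}

#' Significance tier per (CLG, chromosome) cell
#'
#' Reproduces the two-tier annotation of the association grid: a cell is
#' \emph{strong} when its best Bonferroni-corrected 50-gene-window p is
#' < 0.01, \emph{weak} when the 50-gene p is < 0.05, the 100-gene p is
#' < 0.01 or the whole-chromosome p is < 0.05, and \emph{none} otherwise.
#' Strong subsumes weak.
#'
#' @param res50,res100,res_chrom Enrichment tables from
#'   \code{\link{window_enrichment}} (sizes 50 and 100) and
#'   \code{\link{chromosome_enrichment}} for one target species.
#' @return data.frame \code{clg}, \code{target}, \code{chromosome},
#'   \code{p50}, \code{p100}, \code{pchrom}, \code{tier}.
#' @export
significance_tier <- function(res50, res100, res_chrom) {
  s50 <- summarize_enrichment(res50)
  s100 <- summarize_enrichment(res100)
  sch <- summarize_enrichment(res_chrom)
  key <- function(d) paste(d$clg, d$chromosome, sep = "\r")
  cells <- unique(rbind(s50[c("clg", "target", "chromosome")],
                        s100[c("clg", "target", "chromosome")],
                        sch[c("clg", "target", "chromosome")]))
  cells$p50 <- s50$p_bonferroni[match(key(cells), key(s50))]
  cells$p100 <- s100$p_bonferroni[match(key(cells), key(s100))]
  cells$pchrom <- sch$p_bonferroni[match(key(cells), key(sch))]
  p50 <- ifelse(is.na(cells$p50), 1, cells$p50)
  p100 <- ifelse(is.na(cells$p100), 1, cells$p100)
  pch <- ifelse(is.na(cells$pchrom), 1, cells$pchrom)
  cells$tier <- ifelse(p50 < 0.01, "strong",
                       ifelse(p50 < 0.05 | p100 < 0.01 | pch < 0.05,
                              "weak", "none"))
  cells <- cells[order(cells$clg, cells$chromosome), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}
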