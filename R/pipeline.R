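#' Run the full macro-synteny analysis pipeline
#'
#' Orchestrates the stages end-to-end on a dataset (simulated in memory or
#' read from disk): mutual-best-hit orthology, anchor construction, synteny
#' breakpoint detection and linkage-group inference on the outgroup,
#' hypergeometric enrichment at chromosome and window scales, ancestry
#' painting and block partitioning of the ingroup genomes, orthologous-cell
#' assignment, retention fractions, alpha/beta subgenome assignment, the
#' asymmetry bootstrap test, the dip test of retention bimodality,
#' cross-species retention correlations and the fusion-concordance
#' permutation test.  All stage outputs are pure functions of (inputs,
#' config, seed); writing the same dataset with the same configuration twice
#' yields byte-identical files.
#'
#' @param dataset A \code{\link{simulate_genomes}} result or the list
#'   returned by \code{\link{read_dataset}} (gene maps, similarity tables
#'   and orthogroups are required).
#' @param config An \code{\link{analysis_config}}.
#' @param out_dir Optional directory; when given, all result tables plus a
#'   run manifest are written there via \code{\link{write_results}}.
#' @return List of class \code{pipeline_result} with elements
#'   \code{anchors}, \code{breakpoints}, \code{partition},
#'   \code{enrichment} (per scale), \code{tiers}, \code{painting},
#'   \code{blocks}, \code{cells}, \code{retention}, \code{pairs},
#'   \code{asymmetry}, \code{dip}, \code{correlations},
#'   \code{fusion_concordance}, \code{tables} (the flat TSV-ready tables).
#' @export
run_pipeline <- function(dataset, config = analysis_config(),
                         out_dir = NULL) {
  gene_maps <- dataset$gene_maps
  stopifnot("outgroup" %in% names(gene_maps))
  ingroups <- setdiff(names(gene_maps), "outgroup")
  # orthology
  mbh <- lapply(ingroups, function(sp) {
    s <- dataset$similarity[[sp]]
    if (is.null(s)) stop("stage orthology: no similarity tables for ", sp)
    mutual_best_hits(s$fwd, s$rev)
  })
  names(mbh) <- ingroups
  anchors <- build_anchor_set(gene_maps$outgroup, mbh, gene_maps)
  # linkage-group inference on the outgroup
  bps <- consensus_breakpoints(anchors, ingroups, W = config$W,
                               threshold = config$peak_threshold,
                               min_separation = config$min_separation)
  segments <- segment_chromosomes(anchors, bps)
  partition <- merge_segments(anchors, segments, ingroups,
                              threshold = config$merge_threshold)
  # enrichment per ingroup and scale
  enrich <- list()
  tiers <- list()
  for (sp in ingroups) {
    e50 <- window_enrichment(partition, anchors, sp,
                             window_size = config$enrich_windows[1L],
                             step = config$enrich_step[1L],
                             levels = config$alpha_levels)
    e100 <- window_enrichment(partition, anchors, sp,
                              window_size = config$enrich_windows[2L],
                              step = config$enrich_step[2L],
                              levels = config$alpha_levels)
    ech <- chromosome_enrichment(partition, anchors, sp,
                                 levels = config$alpha_levels)
    enrich[[sp]] <- list(window50 = e50, window100 = e100, chromosome = ech)
    tiers[[sp]] <- significance_tier(e50, e100, ech)
  }
  # ancestry painting and blocks
  ancestries <- lapply(ingroups, function(sp)
    clg_gene_ancestry(gene_maps[[sp]], dataset$orthogroups, partition,
                      "outgroup"))
  names(ancestries) <- ingroups
  painting <- lapply(ancestries, paint_windows,
                     min_window = config$paint_min_window)
  blocks <- lapply(ancestries, partition_blocks,
                   min_gap = config$paint_min_window,
                   threshold = config$peak_threshold)
  cells <- assign_copies(blocks, ancestries)
  retention <- retention_fractions(cells, partition, dataset$orthogroups,
                                   ancestries, "outgroup",
                                   outgroup_map = gene_maps$outgroup)
  retention <- assign_alpha_beta(retention)
  pairs <- retention_pairs(retention)
  asym <- if (nrow(pairs) >= 2L)
    asymmetry_test(pairs, reps = config$bootstrap_reps,
                   seed = config$seed) else NULL
  measured <- retention$retention[retention$subgenome %in%
                                    c("alpha", "beta", "alpha_no_beta")]
  dip <- if (length(measured) >= 4L)
    dip_test(measured, n_boot = config$dip_boot, seed = config$seed) else NULL
  correlations <- list()
  if (length(ingroups) >= 2L) {
    cmb <- utils::combn(sort(ingroups), 2L)
    for (i in seq_len(ncol(cmb))) {
      r <- retention_correlation(retention, cmb[1L, i], cmb[2L, i])
      correlations[[paste(cmb[1L, i], cmb[2L, i], sep = "-")]] <- r
    }
  }
  fp <- fusion_pairs_by_subgenome(retention)
  fusion <- if (length(fp$beta_segments) >= 2L)
    fusion_concordance_test(fp$alpha, fp$beta, fp$beta_segments,
                            seed = config$seed) else NULL
  tables <- list(
    anchors = anchors$anchors,
    breakpoints = bps,
    clg_assignment = partition$assignment,
    clg_segments = partition$segments,
    enrichment = do.call(rbind, unlist(enrich, recursive = FALSE)),
    tiers = do.call(rbind, tiers),
    painting = do.call(rbind, Map(function(sp, p) cbind(species = sp, p),
                                  names(painting), painting)),
    blocks = do.call(rbind, Map(function(sp, b) cbind(species = sp, b),
                                names(blocks), blocks)),
    cells = cells,
    retention = as.data.frame(retention),
    asymmetry = if (!is.null(asym))
      data.frame(observed = asym$observed, null_mean = asym$null_mean,
                 null_sd = asym$null_sd, z = asym$z, p = asym$p,
                 c_upper = asym$c_upper, m = asym$m, reps = asym$reps)
      else data.frame(),
    dip = if (!is.null(dip))
      data.frame(D = dip$statistic, p = dip$p, n = dip$n,
                 n_boot = dip$n_boot) else data.frame(),
    correlations = if (length(correlations))
      data.frame(pair = names(correlations),
                 r = vapply(correlations, function(x) x$r, numeric(1)),
                 n = vapply(correlations, function(x) x$n, numeric(1)))
      else data.frame(),
    fusion_concordance = if (!is.null(fusion))
      data.frame(statistic = fusion$statistic, p = fusion$p,
                 n_matchings = fusion$n_matchings, exact = fusion$exact)
      else data.frame())
  if (!is.null(out_dir))
    write_results(tables, out_dir, config,
                  extra = list(n_anchors = nrow(anchors$anchors),
                               n_clgs = length(partition$clg_sizes)))
  structure(list(anchors = anchors, breakpoints = bps, partition = partition,
                 enrichment = enrich, tiers = tiers, painting = painting,
                 blocks = blocks, cells = cells, retention = retention,
                 pairs = pairs, asymmetry = asym, dip = dip,
                 correlations = correlations, fusion_concordance = fusion,
                 tables = tables),
            class = "pipeline_result")
}

#' Fused CLG pairs per subgenome
#'
#' Extracts, from a labelled retention table, the unordered CLG pairs fused
#' pairwise within each subgenome (chromosomes carrying exactly two distinct
#' CLG ancestries, union over species), plus the multiset of beta segments
#' entering those fusions — the inputs of
#' \code{\link{fusion_concordance_test}}.  Chromosomes carrying three or
#' more CLGs (serial fusions) do not define a pairwise matching and are
#' excluded.
#'
#' @param retention Output of \code{\link{assign_alpha_beta}}.
#' @return List: \code{alpha}, \code{beta} (lists of CLG pairs),
#'   \code{beta_segments} (two per beta pair).
#' @export
fusion_pairs_by_subgenome <- function(retention) {
  one <- function(sub) {
    r <- retention[retention$subgenome == sub |
                     (sub == "alpha" & retention$subgenome == "alpha_no_beta"), ]
    key <- paste(r$species, r$chromosome, sep = "\r")
    prs <- character(0)
    for (k in unique(key)) {
      cl <- sort(unique(r$clg[key == k]))
      if (length(cl) == 2L) prs <- c(prs, paste(cl, collapse = "+"))
    }
    unique(prs)
  }
  ap <- one("alpha")
  bp <- one("beta")
  list(alpha = lapply(strsplit(ap, "\\+"), identity),
       beta = lapply(strsplit(bp, "\\+"), identity),
       beta_segments = unlist(strsplit(bp, "\\+")))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: %d anchors, %d breakpoints, ",
                     "%d linkage groups, %d cells\n"),
              nrow(x$anchors$anchors), nrow(x$breakpoints),
              length(x$partition$clg_sizes),
              length(unique(paste(x$cells$clg, x$cells$cell)))))
  invisible(x)
}
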