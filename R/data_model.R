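#' Construct a gene map
#'
#' A gene map is the coordinate system of all downstream analyses: the ordered
#' gene positions on the chromosomes of one species.  All statistics operate on
#' gene ordinals (0-based, consecutive within a chromosome); base-pair
#' coordinates are carried only for display.
#'
#' @param species Species identifier (single string).
#' @param genes A data.frame with columns \code{gene_id}, \code{chromosome} and
#'   optionally \code{bp_start}, \code{bp_end}.  Ordinals are assigned by
#'   sorting on (chromosome, bp_start, gene_id); rows lacking \code{bp_start}
#'   are kept in their input order within each chromosome.
#' @return An object of class \code{gene_map}: a list with elements
#'   \code{species} and \code{genes} (data.frame with columns \code{gene_id},
#'   \code{chromosome}, \code{ordinal}, \code{bp_start}, \code{bp_end}).
#' @export
gene_map <- function(species, genes) {
  stopifnot(is.character(species), length(species) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), chromosome = character(),
                        ordinal = integer(), bp_start = numeric(),
                        bp_end = numeric(), stringsAsFactors = FALSE)
    return(structure(list(species = species, genes = genes),
                     class = "gene_map"))
  }
  stopifnot(all(c("gene_id", "chromosome") %in% names(genes)))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
    stop("duplicate gene_id in gene map for ", species, ": ", dup)
  }
  if (is.null(genes$bp_start)) genes$bp_start <- NA_real_
  if (is.null(genes$bp_end)) genes$bp_end <- NA_real_
  # stable sort: (chromosome, bp_start, gene_id); NA bp_start keeps input order
  ord <- order(genes$chromosome, genes$bp_start, genes$gene_id,
               method = "radix", na.last = TRUE)
  has_bp <- !all(is.na(genes$bp_start))
  if (!has_bp) ord <- order(genes$chromosome, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                              FUN = function(i) seq_along(i) - 1L)
  genes <- genes[, c("gene_id", "chromosome", "ordinal", "bp_start", "bp_end")]
  rownames(genes) <- NULL
  structure(list(species = species, genes = genes), class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("gene_map: %s, %d genes on %d chromosome(s)\n", x$species,
              nrow(x$genes), length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Read a gene map from disk
#'
#' Supported dialects: 4-column TSV (species, chromosome, bp_start, gene_id),
#' BED (chrom, start, end, name) and GFF3 restricted to \code{gene} features
#' (requires the rtracklayer package).  Ordinals are assigned by sorting on
#' (chromosome, bp_start, gene_id), so identical input yields identical maps;
#' ties in bp_start are broken lexicographically by gene id.
#'
#' @param path Path to the file.
#' @param format One of \code{"tsv"}, \code{"bed"}, \code{"gff3"}.
#' @param species Species identifier; for the TSV dialect, defaults to the
#'   value in the first column.
#' @return A \code{\link{gene_map}}.
#' @export
read_gene_map <- function(path, format = c("tsv", "bed", "gff3"),
                          species = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
    df <- data.frame(gene_id = as.character(gr$ID),
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     bp_start = GenomicRanges::start(gr),
                     bp_end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    if (anyNA(df$bp_start)) stop("GFF3 gene feature without coordinates")
    if (is.null(species)) species <- "unknown"
    return(gene_map(species, df))
  }
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) data.frame())
  if (nrow(tab) == 0L) {
    warning("empty gene map file: ", path)
    return(gene_map(if (is.null(species)) "unknown" else species,
                    data.frame(gene_id = character(),
                               chromosome = character())))
  }
  if (format == "bed") {
    if (ncol(tab) < 4L) stop("BED gene map needs >= 4 columns")
    if (!is.numeric(tab[[2L]]) || anyNA(tab[[2L]]))
      stop("missing coordinates in BED gene map")
    df <- data.frame(gene_id = as.character(tab[[4L]]),
                     chromosome = as.character(tab[[1L]]),
                     bp_start = as.numeric(tab[[2L]]),
                     bp_end = as.numeric(tab[[3L]]),
                     stringsAsFactors = FALSE)
    if (is.null(species)) species <- "unknown"
  } else {
    if (ncol(tab) < 4L) stop("TSV gene map needs 4 columns: species, chromosome, bp_start, gene_id")
    df <- data.frame(gene_id = as.character(tab[[4L]]),
                     chromosome = as.character(tab[[2L]]),
                     bp_start = as.numeric(tab[[3L]]),
                     bp_end = NA_real_,
                     stringsAsFactors = FALSE)
    if (is.null(species)) species <- as.character(tab[[1L]][1L])
  }
  gene_map(species, df)
}

#' Construct a similarity table
#'
#' @param from,to Species identifiers for the search direction.
#' @param hits data.frame with columns \code{query}, \code{subject},
#'   \code{score} (bitscore-like, higher is better).  Duplicate (query,
#'   subject) pairs are collapsed keeping the maximum score.
#' @return Object of class \code{similarity_table}.
#' @export
similarity_table <- function(from, to, hits) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    stopifnot(all(c("query", "subject", "score") %in% names(hits)))
    hits$query <- as.character(hits$query)
    hits$subject <- as.character(hits$subject)
    hits$score <- as.numeric(hits$score)
    if (any(!is.finite(hits$score))) stop("non-finite similarity score")
    key <- paste(hits$query, hits$subject, sep = "\r")
    if (anyDuplicated(key)) {
      best <- tapply(hits$score, key, max)
      hits <- hits[!duplicated(key), , drop = FALSE]
      hits$score <- as.numeric(best[paste(hits$query, hits$subject, sep = "\r")])
    }
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(query = character(), subject = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(from = from, to = to, hits = hits),
            class = "similarity_table")
}

#' Read a similarity table
#'
#' Accepts a plain 3-column TSV (query, subject, score) or 12-column tabular
#' alignment output, in which case columns 1, 2 and 12 are used.  Lines
#' starting with '#' are skipped; duplicate (query, subject) pairs are
#' collapsed keeping the maximum score.
#'
#' @param path Path to the file.
#' @param from,to Species identifiers of the search direction.
#' @return A \code{\link{similarity_table}}.
#' @export
read_similarity <- function(path, from, to) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) data.frame())
  if (nrow(tab) == 0L)
    return(similarity_table(from, to, data.frame()))
  score_col <- if (ncol(tab) >= 12L) 12L else 3L
  if (ncol(tab) < 3L) stop("similarity table needs >= 3 columns")
  sc <- suppressWarnings(as.numeric(tab[[score_col]]))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1L]
    stop("non-numeric score at line ", bad, " of ", path)
  }
  similarity_table(from, to,
                   data.frame(query = as.character(tab[[1L]]),
                              subject = as.character(tab[[2L]]),
                              score = sc, stringsAsFactors = FALSE))
}

#' Read an orthogroup (gene family) table
#'
#' Expects a TSV with columns family_id, species, gene_id.  Each gene may
#' belong to at most one family.
#'
#' @param path Path to the TSV.
#' @return data.frame of class \code{orthogroup_table} with columns
#'   \code{family_id}, \code{species}, \code{gene_id}.
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  orthogroup_table(tab)
}

#' @rdname read_orthogroups
#' @param families data.frame with columns \code{family_id}, \code{species},
#'   \code{gene_id}.
#' @export
orthogroup_table <- function(families) {
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "species", "gene_id") %in% names(families)))
  key <- paste(families$species, families$gene_id, sep = "\r")
  if (anyDuplicated(key)) stop("a gene belongs to more than one family")
  class(families) <- c("orthogroup_table", "data.frame")
  families
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline.  Defaults follow the study
#' conditions: discontinuity window \code{W} of 25 genes, ancestry-painting
#' windows of at least 20 genes, enrichment scans with 50- and 100-gene
#' sliding windows.
#'
#' @param W Window size (genes) for the synteny-discontinuity statistic.
#' @param peak_threshold Minimum discontinuity for a breakpoint call, in
#'   (0, 2]; 0.5 corresponds to a 50\% composition switch.
#' @param min_separation Minimum gene separation between breakpoints
#'   (default \code{W}).
#' @param paint_min_window Minimum genes per ancestry-painting window.
#' @param enrich_windows Sliding-window sizes (genes) for enrichment scans.
#' @param enrich_step Step between window starts (default half the window).
#' @param alpha_levels Significance levels used for reporting tiers.
#' @param merge_threshold Cosine-similarity threshold for merging segments
#'   into one linkage group.
#' @param bootstrap_reps Bootstrap replicates for the asymmetry null.
#' @param dip_boot Bootstrap replicates for the dip-test null.
#' @param seed Integer seed; all randomness in a run flows from it.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(W = 25L, peak_threshold = 0.5,
                            min_separation = W, paint_min_window = 20L,
                            enrich_windows = c(50L, 100L),
                            enrich_step = NULL,
                            alpha_levels = c(0.01, 0.05),
                            merge_threshold = 0.75,
                            bootstrap_reps = 1e6, dip_boot = 1e4,
                            seed = 1L) {
  stopifnot(W >= 2, paint_min_window >= 2, all(enrich_windows >= 2),
            peak_threshold > 0, peak_threshold <= 2, bootstrap_reps >= 1,
            min_separation >= 1)
  if (is.null(enrich_step)) enrich_step <- as.integer(enrich_windows / 2)
  structure(list(W = as.integer(W), peak_threshold = peak_threshold,
                 min_separation = as.integer(min_separation),
                 paint_min_window = as.integer(paint_min_window),
                 enrich_windows = as.integer(enrich_windows),
                 enrich_step = as.integer(enrich_step),
                 alpha_levels = alpha_levels,
                 merge_threshold = merge_threshold,
                 bootstrap_reps = bootstrap_reps, dip_boot = dip_boot,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   \code{\link{analysis_config}}.
#' @return An \code{analysis_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}

#' Write result tables and a run manifest
#'
#' Writes each table as a TSV with a fixed column order plus a
#' \code{manifest.json} recording the configuration, seed and md5 digests of
#' the outputs.  Identical inputs, configuration and seed produce
#' byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config An \code{analysis_config} (stored in the manifest).
#' @param extra Optional named list of extra manifest entries.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, config = analysis_config(),
                          extra = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths[nm] <- p
  }
  cfg <- unclass(config)
  manifest <- c(list(
    config = cfg,
    config_digest = digest_object(cfg),
    seed = config$seed,
    unplaced_genes = "excluded from all counts",
    files = lapply(paths, function(p) unname(tools::md5sum(p)))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# plain deterministic TSV writer (header always present, '.' for NA)
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv <- function(path) {
  tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = ".", quote = "",
                      comment.char = ""),
    error = function(e) data.frame())
}

# md5 of a canonical serialization, used to detect config drift across runs
digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a gene map as 4-column TSV
#'
#' The canonical interchange dialect: species, chromosome, bp_start, gene_id.
#' Maps written then re-read reproduce the object exactly (a bp coordinate of
#' 1000*(ordinal+1) is synthesised when missing so ordering round-trips).
#'
#' @param gm A \code{gene_map}.
#' @param path Output path.
#' @export
write_gene_map <- function(gm, path) {
  g <- gm$genes
  bp <- ifelse(is.na(g$bp_start), 1000 * (g$ordinal + 1), g$bp_start)
  utils::write.table(data.frame(gm$species, g$chromosome, bp, g$gene_id),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
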