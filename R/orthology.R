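#' Mutual best hits between two species
#'
#' A pair (a, b) is returned iff b is a's unique top-scoring subject in the
#' forward search and a is b's unique top-scoring subject in the reverse
#' search.  A gene whose top score is shared by two or more subjects has no
#' unique best and is excluded: reciprocal best hits are meant to be a
#' conservative set of orthologues, and ambiguity disqualifies.
#'
#' @param fwd,rev \code{\link{similarity_table}}s covering the same species
#'   pair in opposite directions.
#' @return Object of class \code{orthology_table}: list with \code{species}
#'   (character vector \code{c(from, to)} of \code{fwd}) and \code{pairs}
#'   (data.frame \code{gene_a}, \code{gene_b}), a 1:1 mapping.
#' @export
mutual_best_hits <- function(fwd, rev) {
  stopifnot(inherits(fwd, "similarity_table"), inherits(rev, "similarity_table"))
  if (!identical(c(fwd$from, fwd$to), c(rev$to, rev$from)))
    stop("similarity tables do not cover the same species pair in opposite directions")
  bf <- unique_best(fwd$hits)   # query -> subject
  br <- unique_best(rev$hits)
  if (nrow(bf) == 0L || nrow(br) == 0L) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  } else {
    m <- merge(bf, data.frame(subject = br$query, back = br$subject,
                              stringsAsFactors = FALSE), by = "subject")
    m <- m[m$query == m$back, , drop = FALSE]
    pairs <- data.frame(gene_a = m$query, gene_b = m$subject,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(species = c(fwd$from, fwd$to), pairs = pairs),
            class = "orthology_table")
}

# per query: its subject iff the top score is attained uniquely
unique_best <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query = character(), subject = character(),
                      stringsAsFactors = FALSE))
  sp <- split(seq_len(nrow(hits)), hits$query)
  keep <- vapply(sp, function(i) {
    s <- hits$score[i]
    top <- max(s)
    if (sum(s == top) != 1L) NA_integer_ else i[which.max(s)]
  }, integer(1))
  keep <- keep[!is.na(keep)]
  data.frame(query = hits$query[keep], subject = hits$subject[keep],
             stringsAsFactors = FALSE)
}

#' Build an anchor set from an outgroup gene map and per-target orthologies
#'
#' Anchors are outgroup genes with a mutual-best-hit orthologue in at least
#' one target species, ordered along the outgroup genome by
#' (chromosome, ordinal).  Genes with no orthologue anywhere are dropped.
#'
#' @param outgroup A \code{\link{gene_map}} of the unduplicated outgroup.
#' @param mbh_tables Named list of \code{orthology_table}s, one per target
#'   species; the outgroup must be one member of each pair (either side).
#' @param target_maps Named list of target \code{gene_map}s, used to annotate
#'   each orthologue with its chromosome and ordinal.
#' @return Object of class \code{anchor_set}: list with \code{outgroup},
#'   \code{targets} and \code{anchors}, a data.frame with columns
#'   \code{outgroup_gene}, \code{chromosome}, \code{ordinal} and, per target
#'   t, \code{gene.t}, \code{chrom.t}, \code{ord.t} (NA when absent).
#' @export
build_anchor_set <- function(outgroup, mbh_tables, target_maps) {
  stopifnot(inherits(outgroup, "gene_map"), length(mbh_tables) >= 1L)
  targets <- names(mbh_tables)
  stopifnot(!is.null(targets), all(targets %in% names(target_maps)))
  anc <- outgroup$genes[, c("gene_id", "chromosome", "ordinal")]
  names(anc)[1L] <- "outgroup_gene"
  for (t in targets) {
    ot <- mbh_tables[[t]]
    stopifnot(inherits(ot, "orthology_table"))
    if (!outgroup$species %in% ot$species)
      stop("orthology table for ", t, " does not involve the outgroup")
    p <- ot$pairs
    if (ot$species[1L] != outgroup$species)
      p <- data.frame(gene_a = p$gene_b, gene_b = p$gene_a,
                      stringsAsFactors = FALSE)
    tg <- target_maps[[t]]$genes
    idx <- match(anc$outgroup_gene, p$gene_a)
    gid <- p$gene_b[idx]
    tidx <- match(gid, tg$gene_id)
    anc[[paste0("gene.", t)]] <- gid
    anc[[paste0("chrom.", t)]] <- tg$chromosome[tidx]
    anc[[paste0("ord.", t)]] <- tg$ordinal[tidx]
  }
  has_any <- Reduce(`|`, lapply(targets, function(t)
    !is.na(anc[[paste0("gene.", t)]])))
  anc <- anc[has_any, , drop = FALSE]
  anc <- anc[order(anc$chromosome, anc$ordinal, method = "radix"), , drop = FALSE]
  rownames(anc) <- NULL
  structure(list(outgroup = outgroup$species, targets = targets,
                 anchors = anc),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d anchors, outgroup %s, targets: %s\n",
              nrow(x$anchors), x$outgroup, paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Count a gene family once per chromosome
#'
#' The retention analysis counts only one family member per chromosome, so
#' tandem (linked) duplications do not inflate retention values while
#' unlinked duplicates created by chromosome-scale events are counted.
#'
#' @param family Character vector of gene ids forming one family.
#' @param gmap A \code{\link{gene_map}} for the species in question.
#' @return Named integer vector: 1 per chromosome carrying at least one
#'   family member.
#' @export
collapse_per_chromosome <- function(family, gmap) {
  g <- gmap$genes
  chrom <- g$chromosome[match(family, g$gene_id)]
  chrom <- chrom[!is.na(chrom)]
  if (!length(chrom)) return(stats::setNames(integer(0), character(0)))
  u <- sort(unique(chrom))
  stats::setNames(rep(1L, length(u)), u)
}
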