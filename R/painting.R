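#' Map genes of a duplicated genome to CLG ancestries via gene families
#'
#' A target gene inherits the CLG of its family, defined as the majority CLG
#' of the family's outgroup members under the partition (families whose
#' outgroup members are unassigned contribute nothing).
#'
#' @param gmap Target \code{\link{gene_map}}.
#' @param orthogroups An \code{\link{orthogroup_table}}.
#' @param partition A \code{\link{merge_segments}} result for the outgroup.
#' @param outgroup Outgroup species name as used in the orthogroup table.
#' @return data.frame \code{gene_id}, \code{chromosome}, \code{ordinal},
#'   \code{family_id}, \code{clg} (NA when unknown), ordered along the genome.
#' @export
clg_gene_ancestry <- function(gmap, orthogroups, partition, outgroup) {
  og <- orthogroups[orthogroups$species == outgroup, , drop = FALSE]
  og$clg <- partition$assignment$clg[match(og$gene_id,
                                           partition$assignment$gene_id)]
  og <- og[!is.na(og$clg), , drop = FALSE]
  fam_clg <- vapply(split(og$clg, og$family_id), function(cl)
    names(sort(table(cl), decreasing = TRUE))[1L], character(1))
  tg <- orthogroups[orthogroups$species == gmap$species, , drop = FALSE]
  g <- gmap$genes
  g$family_id <- tg$family_id[match(g$gene_id, tg$gene_id)]
  g$clg <- unname(fam_clg[g$family_id])
  g[, c("gene_id", "chromosome", "ordinal", "family_id", "clg")]
}

#' Paint chromosomes by local CLG ancestry
#'
#' Tiles each chromosome with non-overlapping windows of at least
#' \code{min_window} genes and reports the fraction of genes of each CLG
#' ancestry per window.  Genes without a CLG-anchored family contribute no
#' mass, so fractions sum to at most 1.
#'
#' @param ancestry Output of \code{\link{clg_gene_ancestry}}.
#' @param min_window Minimum genes per window (default 20).
#' @return data.frame \code{chromosome}, \code{window}, \code{start_ordinal},
#'   \code{end_ordinal} (half-open), \code{n_genes}, \code{clg},
#'   \code{fraction}, long format with one row per (window, CLG present).
#' @export
paint_windows <- function(ancestry, min_window = 20L) {
  out <- lapply(split(ancestry, ancestry$chromosome), function(g) {
    g <- g[order(g$ordinal), , drop = FALSE]
    n <- nrow(g)
    k <- max(1L, n %/% min_window)
    if (n < min_window)
      warning("chromosome ", g$chromosome[1L], " has fewer than ",
              min_window, " genes; single whole-chromosome window")
    bounds <- round(seq(0L, n, length.out = k + 1L))
    do.call(rbind, lapply(seq_len(k), function(w) {
      idx <- (bounds[w] + 1L):bounds[w + 1L]
      cl <- g$clg[idx]
      tab <- table(cl[!is.na(cl)])
      if (!length(tab))
        return(data.frame(chromosome = g$chromosome[1L], window = w,
                          start_ordinal = g$ordinal[idx[1L]],
                          end_ordinal = g$ordinal[idx[length(idx)]] + 1L,
                          n_genes = length(idx), clg = NA_character_,
                          fraction = 0, stringsAsFactors = FALSE))
      data.frame(chromosome = g$chromosome[1L], window = w,
                 start_ordinal = g$ordinal[idx[1L]],
                 end_ordinal = g$ordinal[idx[length(idx)]] + 1L,
                 n_genes = length(idx), clg = names(tab),
                 fraction = as.numeric(tab) / length(idx),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partition chromosomes into blocks of homogeneous CLG ancestry
#'
#' Runs the synteny-discontinuity statistic on the CLG-label sequence of each
#' chromosome (CLGs playing the role of comparator chromosomes) and splits
#' recursively at the largest remaining peak, rejecting candidates within
#' \code{min_gap} genes of an accepted breakpoint, until no peak of at least
#' \code{threshold} remains.  Blocks tile the chromosome exactly.
#'
#' @param ancestry Output of \code{\link{clg_gene_ancestry}}.
#' @param min_gap Minimum genes between breakpoints and window size of the
#'   discontinuity statistic (default 20).
#' @param threshold Stopping threshold on the discontinuity peak.
#' @return data.frame of blocks: \code{chromosome}, \code{block},
#'   \code{start_ordinal}, \code{end_ordinal} (half-open over the whole
#'   chromosome), \code{n_genes} (genes with known ancestry),
#'   \code{dominant_clg}, \code{purity}, \code{clgs} (comma-joined CLGs with
#'   fraction >= 0.1 of assigned genes).
#' @export
partition_blocks <- function(ancestry, min_gap = 20L, threshold = 0.5) {
  out <- lapply(split(ancestry, ancestry$chromosome), function(g) {
    g <- g[order(g$ordinal), , drop = FALSE]
    ga <- g[!is.na(g$clg), , drop = FALSE]
    n <- nrow(ga)
    chrom_end <- max(g$ordinal) + 1L
    if (n < 2L)
      return(block_row(g$chromosome[1L], 1L, min(g$ordinal), chrom_end, ga))
    clgs <- sort(unique(ga$clg))
    m <- matrix(0, n, length(clgs))
    m[cbind(seq_len(n), match(ga$clg, clgs))] <- 1
    wm <- windowed_means(m, min_gap)
    i <- seq_len(n - 1L)
    D <- rowSums((wm$XR[i + 1L, , drop = FALSE] - wm$XL[i, , drop = FALSE])^2)
    edge <- ceiling(min_gap / 2)
    eligible <- (i >= edge) & ((n - i) >= edge)
    # iterative largest-peak acceptance with a min_gap exclusion zone
    acc <- integer(0)
    repeat {
      cand <- which(eligible & D >= threshold)
      if (length(acc))
        cand <- cand[vapply(cand, function(j)
          all(abs(acc - j) >= min_gap), logical(1))]
      if (!length(cand)) break
      acc <- c(acc, cand[which.max(D[cand])])
    }
    acc <- sort(acc)
    # a boundary between two blocks of the same dominant ancestry is not an
    # ancestry boundary (mixing artefact); drop it
    repeat {
      bounds <- c(0L, acc, n)
      dom <- vapply(seq_len(length(bounds) - 1L), function(b) {
        cl <- ga$clg[(bounds[b] + 1L):bounds[b + 1L]]
        names(sort(table(cl), decreasing = TRUE))[1L]
      }, character(1))
      same <- which(dom[-length(dom)] == dom[-1L])
      if (!length(same) || !length(acc)) break
      acc <- acc[-same[1L]]
    }
    bounds <- c(0L, acc, n)
    blocks <- lapply(seq_len(length(bounds) - 1L), function(b) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      start <- if (b == 1L) min(g$ordinal) else ga$ordinal[bounds[b] + 1L]
      end <- if (b == length(bounds) - 1L) chrom_end
             else ga$ordinal[bounds[b + 1L] + 1L]
      block_row(g$chromosome[1L], b, start, end, ga[idx, , drop = FALSE])
    })
    do.call(rbind, blocks)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

block_row <- function(chrom, b, start, end, ga) {
  if (nrow(ga) == 0L)
    return(data.frame(chromosome = chrom, block = b, start_ordinal = start,
                      end_ordinal = end, n_genes = 0L,
                      dominant_clg = NA_character_, purity = NA_real_,
                      clgs = "", stringsAsFactors = FALSE))
  tab <- sort(table(ga$clg), decreasing = TRUE)
  frac <- tab / sum(tab)
  data.frame(chromosome = chrom, block = b, start_ordinal = start,
             end_ordinal = end, n_genes = nrow(ga),
             dominant_clg = names(tab)[1L],
             purity = as.numeric(frac[1L]),
             clgs = paste(sort(names(frac)[frac >= 0.1]), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Group ancestry blocks across species into orthologous cells
#'
#' For each CLG, blocks of that dominant ancestry are linked across ingroup
#' species into orthologous cells by majority orthologue (gene-family)
#' sharing: the species with most blocks seeds the cells and each other
#' species' blocks join the cell with which they share most families, greedily
#' in decreasing shared-count order.  Paralogous cells of one CLG are
#' enumerated as distinct copies; two same-CLG blocks on one chromosome stay
#' distinct cells (sub-labels a/b).  A block tied between two cells is flagged
#' ambiguous and excluded from retention pairing.  The fusion pattern of a
#' cell is the set of other dominant CLGs co-resident on its chromosome,
#' taken as the majority pattern across its species.
#'
#' @param blocks Named list (per species) of \code{\link{partition_blocks}}
#'   outputs.
#' @param ancestries Named list (per species) of
#'   \code{\link{clg_gene_ancestry}} outputs (for family sharing).
#' @param min_genes Blocks with fewer assigned genes are ignored (default 10).
#' @return data.frame of cells x species: \code{clg}, \code{cell} (integer
#'   copy index within CLG), \code{sublabel}, \code{species},
#'   \code{chromosome}, \code{block}, \code{start_ordinal},
#'   \code{end_ordinal}, \code{n_genes}, \code{fusion_pattern},
#'   \code{ambiguous}.
#' @export
assign_copies <- function(blocks, ancestries, min_genes = 10L) {
  species <- names(blocks)
  stopifnot(length(species) >= 2L, identical(sort(species),
                                             sort(names(ancestries))))
  # families per block
  blk <- lapply(species, function(s) {
    b <- blocks[[s]]
    b <- b[!is.na(b$dominant_clg) & b$n_genes >= min_genes, , drop = FALSE]
    b$species <- s
    anc <- ancestries[[s]]
    b$fams <- lapply(seq_len(nrow(b)), function(i) {
      sel <- anc$chromosome == b$chromosome[i] &
        anc$ordinal >= b$start_ordinal[i] & anc$ordinal < b$end_ordinal[i] &
        !is.na(anc$family_id) & !is.na(anc$clg) & anc$clg == b$dominant_clg[i]
      unique(anc$family_id[sel])
    })
    b
  })
  names(blk) <- species
  rows <- list()
  for (cl in sort(unique(unlist(lapply(blk, function(b) b$dominant_clg))))) {
    per_sp <- lapply(blk, function(b) b[b$dominant_clg == cl, , drop = FALSE])
    counts <- vapply(per_sp, nrow, 1L)
    if (!any(counts > 0L)) next
    seed_sp <- species[order(-counts, species)][1L]
    seed <- per_sp[[seed_sp]]
    ncell <- nrow(seed)
    cells <- lapply(seq_len(ncell), function(i)
      list(fams = seed$fams[[i]],
           members = cbind(seed[i, c("species", "chromosome", "block",
                                     "start_ordinal", "end_ordinal",
                                     "n_genes", "clgs")],
                           cell = i, ambiguous = FALSE)))
    for (s in setdiff(species[order(species)], seed_sp)) {
      b <- per_sp[[s]]
      if (!nrow(b)) next
      sh <- matrix(0L, nrow(b), ncell)
      for (i in seq_len(nrow(b))) for (j in seq_len(ncell))
        sh[i, j] <- length(intersect(b$fams[[i]], cells[[j]]$fams))
      taken <- rep(FALSE, ncell)
      ord <- order(-apply(sh, 1L, max), b$chromosome, b$block)
      for (i in ord) {
        avail <- which(!taken)
        if (!length(avail)) {  # extra block: becomes a new cell
          ncell <- ncell + 1L
          cells[[ncell]] <- list(fams = b$fams[[i]],
                                 members = cbind(b[i, c("species", "chromosome",
                                                        "block", "start_ordinal",
                                                        "end_ordinal", "n_genes",
                                                        "clgs")],
                                                 cell = ncell,
                                                 ambiguous = FALSE))
          taken <- c(taken, TRUE)
          next
        }
        best <- avail[order(-sh[i, avail], avail)]
        amb <- length(best) > 1L && sh[i, best[1L]] == sh[i, best[2L]] &&
          sh[i, best[1L]] > 0L
        j <- best[1L]
        taken[j] <- TRUE
        cells[[j]]$members <- rbind(cells[[j]]$members,
                                    cbind(b[i, c("species", "chromosome",
                                                 "block", "start_ordinal",
                                                 "end_ordinal", "n_genes",
                                                 "clgs")],
                                          cell = j, ambiguous = amb))
        cells[[j]]$fams <- union(cells[[j]]$fams, b$fams[[i]])
      }
    }
    for (j in seq_along(cells)) {
      mem <- cells[[j]]$members
      mem$clg <- cl
      rows[[length(rows) + 1L]] <- mem
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # sub-label same-CLG cells sharing a chromosome within one species
  out$sublabel <- ""
  key <- paste(out$species, out$chromosome, out$clg, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    out$sublabel[idx] <- letters[seq_along(idx)]
  }
  # fusion pattern: majority set of co-resident dominant CLGs across species
  out$fusion_pattern <- cell_fusion_patterns(out)
  out[order(out$clg, out$cell, out$species), ]
}

# majority (by species vote) set of other dominant CLGs sharing a chromosome
cell_fusion_patterns <- function(cells) {
  partners_one <- function(i) {
    same_chrom <- cells$species == cells$species[i] &
      cells$chromosome == cells$chromosome[i]
    setdiff(unique(cells$clg[same_chrom]), cells$clg[i])
  }
  per_row <- lapply(seq_len(nrow(cells)), partners_one)
  out <- character(nrow(cells))
  for (cl in unique(cells$clg)) for (cid in unique(cells$cell[cells$clg == cl])) {
    idx <- which(cells$clg == cl & cells$cell == cid)
    votes <- table(unlist(per_row[idx]))
    maj <- names(votes)[votes > length(idx) / 2]
    if (!length(maj) && length(votes))  # ties: union, deterministic order
      maj <- sort(names(votes)[votes == max(votes)])
    out[idx] <- paste(sort(maj), collapse = "+")
  }
  out
}
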