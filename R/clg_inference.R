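#' Synteny indicator profile against one comparator
#'
#' For each anchor gene of the outgroup with an orthologue in the comparator
#' species, the indicator vector x_a(i) is 1 for the comparator chromosome a
#' carrying the orthologue and 0 elsewhere.
#'
#' @param anchors An \code{\link{anchor_set}}.
#' @param comparator One of the anchor set's target species.
#' @return Object of class \code{synteny_indicator}: list with
#'   \code{comparator}, \code{chromosomes} (comparator chromosome names, the
#'   columns) and \code{genes}, a data.frame (\code{outgroup_gene},
#'   \code{chromosome}, \code{ordinal}, \code{col}) with \code{col} the
#'   1-based index of the comparator chromosome.  Anchors without an
#'   orthologue in this comparator are skipped.
#' @export
indicator_profile <- function(anchors, comparator) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (!comparator %in% anchors$targets)
    stop("comparator ", comparator, " is not among the anchor targets")
  a <- anchors$anchors
  cc <- a[[paste0("chrom.", comparator)]]
  keep <- !is.na(cc)
  g <- a[keep, c("outgroup_gene", "chromosome", "ordinal")]
  chroms <- sort(unique(cc[keep]))
  g$col <- match(cc[keep], chroms)
  rownames(g) <- NULL
  structure(list(comparator = comparator, chromosomes = chroms, genes = g),
            class = "synteny_indicator")
}

# dense 0/1 matrix (anchors x comparator chromosomes) for one outgroup chromosome
indicator_matrix <- function(ind, chromosome) {
  g <- ind$genes[ind$genes$chromosome == chromosome, , drop = FALSE]
  m <- matrix(0, nrow(g), length(ind$chromosomes))
  if (nrow(g)) m[cbind(seq_len(nrow(g)), g$col)] <- 1
  m
}

# windowed means over the W rows ending at (XL) / starting at (XR) each row,
# truncated to the available rows near the ends
windowed_means <- function(m, W) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  i <- seq_len(n)
  lo <- pmax(0L, i - W)           # XL(i): rows (i-W+1)..i  -> cs[i+1]-cs[lo+1]
  hi <- pmin(n, i + W - 1L)       # XR(i): rows i..(i+W-1)  -> cs[hi+1]-cs[i]
  XL <- (cs[i + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (i - lo)
  XR <- (cs[hi + 1L, , drop = FALSE] - cs[i, , drop = FALSE]) / (hi - i + 1L)
  list(XL = XL, XR = XR)
}

#' Synteny discontinuity profile along outgroup chromosomes
#'
#' For adjacent anchors i, i+1 on a chromosome the discontinuity is the
#' squared Euclidean norm of the difference between the right windowed average
#' at i+1 and the left windowed average at i:
#' D(i, i+1) = sum_a (X^R_a(i+1) - X^L_a(i))^2, where X^L_a(i) is the mean of
#' the indicator x_a over the W anchors ending at i and X^R_a(i) the mean over
#' the W anchors starting at i.  Windows near chromosome ends are truncated to
#' the available anchors.  D lies in [0, 2]; it is 0 when both windows have
#' identical composition and reaches 2 only for a complete switch from one
#' comparator chromosome to another.
#'
#' @param ind A \code{\link{indicator_profile}} result.
#' @param W Window size in anchors (>= 2).
#' @return Object of class \code{discontinuity_profile}: data.frame with
#'   columns \code{chromosome}, \code{junction} (index i of the left anchor,
#'   1-based within the chromosome's anchors), \code{ordinal_left},
#'   \code{ordinal_right} (outgroup gene ordinals flanking the junction),
#'   \code{D} and \code{eligible} (FALSE within ceiling(W/2) anchors of a
#'   chromosome end, where truncation makes peaks untrustworthy).
#' @export
discontinuity <- function(ind, W = 25L) {
  stopifnot(inherits(ind, "synteny_indicator"), W >= 2)
  out <- lapply(unique(ind$genes$chromosome), function(chr) {
    g <- ind$genes[ind$genes$chromosome == chr, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) return(NULL)
    m <- indicator_matrix(ind, chr)
    wm <- windowed_means(m, W)
    i <- seq_len(n - 1L)
    D <- rowSums((wm$XR[i + 1L, , drop = FALSE] -
                  wm$XL[i, , drop = FALSE])^2)
    edge <- ceiling(W / 2)
    data.frame(chromosome = chr, junction = i,
               ordinal_left = g$ordinal[i], ordinal_right = g$ordinal[i + 1L],
               D = D, eligible = (i >= edge) & ((n - i) >= edge),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chromosome = character(), junction = integer(),
                      ordinal_left = integer(), ordinal_right = integer(),
                      D = numeric(), eligible = logical())
  class(out) <- c("discontinuity_profile", "data.frame")
  out
}

#' Detect synteny breakpoints as local peaks of the discontinuity profile
#'
#' Local maxima of D with D >= theta are accepted greedily in decreasing D
#' order subject to a pairwise separation of at least \code{min_separation}
#' anchors; junctions too close to chromosome ends are not eligible.
#'
#' @param profile A \code{\link{discontinuity}} result.
#' @param threshold Peak threshold theta in (0, 2].
#' @param min_separation Minimum anchor separation between accepted peaks.
#' @return data.frame with columns \code{chromosome}, \code{junction},
#'   \code{ordinal_left}, \code{ordinal_right}, \code{D}, ordered by
#'   (chromosome, junction).  The breakpoint lies between
#'   \code{ordinal_left} and \code{ordinal_right}.
#' @export
detect_breakpoints <- function(profile, threshold = 0.5, min_separation = 25L) {
  stopifnot(threshold > 0, threshold <= 2, min_separation >= 1)
  res <- lapply(split(profile, profile$chromosome), function(p) {
    p <- p[order(p$junction), , drop = FALSE]
    D <- p$D
    n <- length(D)
    if (!n) return(NULL)
    left <- c(-Inf, D[-n])
    right <- c(D[-1L], -Inf)
    cand <- which(D >= threshold & D >= left & D >= right & p$eligible)
    if (!length(cand)) return(NULL)
    cand <- cand[order(-D[cand], cand)]
    acc <- integer(0)
    for (j in cand) {
      if (!length(acc) || all(abs(p$junction[acc] - p$junction[j]) >= min_separation))
        acc <- c(acc, j)
    }
    p[sort(acc), c("chromosome", "junction", "ordinal_left", "ordinal_right", "D")]
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chromosome = character(), junction = integer(),
                      ordinal_left = integer(), ordinal_right = integer(),
                      D = numeric())
  rownames(out) <- NULL
  out
}

#' Consensus breakpoints across comparator species
#'
#' Breakpoints are called per comparator and pooled; calls within
#' \code{tolerance} anchors of each other (single linkage) form one candidate
#' boundary, which is retained when supported by at least \code{min_support}
#' distinct comparators.  The consensus junction is the D-weighted median of
#' the member calls.
#'
#' @param anchors An \code{\link{anchor_set}}.
#' @param comparators Character vector of target species to use.
#' @param W,threshold,min_separation Passed to \code{\link{discontinuity}} and
#'   \code{\link{detect_breakpoints}}.
#' @param tolerance Clustering tolerance in anchors (default W/2).
#' @param min_support Minimum number of supporting comparators (default 2,
#'   or 1 when only one comparator is supplied).
#' @return data.frame with columns \code{chromosome}, \code{junction},
#'   \code{D} (mean over supporters), \code{support},
#'   \code{comparators} (comma-joined).
#' @export
consensus_breakpoints <- function(anchors, comparators = anchors$targets,
                                  W = 25L, threshold = 0.5,
                                  min_separation = W,
                                  tolerance = ceiling(W / 2),
                                  min_support = min(2L, length(comparators))) {
  calls <- lapply(comparators, function(cmp) {
    bp <- detect_breakpoints(discontinuity(indicator_profile(anchors, cmp), W),
                             threshold, min_separation)
    if (nrow(bp)) bp$comparator <- cmp
    bp
  })
  calls <- do.call(rbind, calls[vapply(calls, nrow, 1L) > 0])
  if (is.null(calls) || !nrow(calls))
    return(data.frame(chromosome = character(), junction = integer(),
                      D = numeric(), support = integer(),
                      comparators = character()))
  res <- lapply(split(calls, calls$chromosome), function(p) {
    p <- p[order(p$junction), , drop = FALSE]
    grp <- cumsum(c(1L, diff(p$junction) > tolerance))
    do.call(rbind, lapply(split(p, grp), function(q) {
      supp <- unique(q$comparator)
      j <- weighted_median(q$junction, q$D)
      sel <- q$junction == j
      data.frame(chromosome = q$chromosome[1L], junction = j,
                 ordinal_left = q$ordinal_left[sel][1L],
                 ordinal_right = q$ordinal_right[sel][1L],
                 D = mean(q$D), support = length(supp),
                 comparators = paste(sort(supp), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chromosome, out$junction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Cut outgroup chromosomes into segments at consensus breakpoints
#'
#' @param anchors An \code{\link{anchor_set}}.
#' @param breakpoints Output of \code{\link{consensus_breakpoints}} (anchor
#'   junction indices per chromosome).
#' @return data.frame of segments: \code{chromosome}, \code{start_anchor},
#'   \code{end_anchor} (half-open, 1-based anchor indices within the
#'   chromosome), \code{start_ordinal}, \code{end_ordinal} (half-open gene
#'   ordinals), \code{n_anchors}, \code{segment_id}.
#' @export
segment_chromosomes <- function(anchors, breakpoints) {
  a <- anchors$anchors
  segs <- lapply(unique(a$chromosome), function(chr) {
    g <- a[a$chromosome == chr, , drop = FALSE]
    n <- nrow(g)
    cuts <- sort(breakpoints$junction[breakpoints$chromosome == chr])
    bounds <- c(0L, cuts, n)
    data.frame(chromosome = chr,
               start_anchor = head(bounds, -1L) + 1L,
               end_anchor = bounds[-1L] + 1L,
               start_ordinal = g$ordinal[head(bounds, -1L) + 1L],
               end_ordinal = c(g$ordinal[cuts + 1L], g$ordinal[n] + 1L),
               n_anchors = diff(bounds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  out$segment_id <- sprintf("%s:%d", out$chromosome, out$start_anchor)
  rownames(out) <- NULL
  out
}

#' Merge syntenic segments into conserved linkage groups
#'
#' Segments whose mean synteny-indicator vectors are closely aligned (cosine
#' similarity >= \code{threshold}) in a majority of comparators are combined
#' into a single syntenic unit by single-linkage merging.  The default
#' threshold 0.75 sits midway between the profile of two segments of one
#' linkage group (cosine near 1) and that of two linkage groups sharing a
#' single fusion in the comparators (cosine near 0.5).  Units are lettered
#' A, B, C, ... in decreasing order of anchor count (ties broken by smallest
#' chromosome identifier).
#'
#' @param anchors An \code{\link{anchor_set}}.
#' @param segments Output of \code{\link{segment_chromosomes}}.
#' @param comparators Target species used for the comparison.
#' @param threshold Cosine-similarity threshold (default 0.75).
#' @param manual_merges Optional list of character vectors of segment ids to
#'   force into one unit (reproducing curated groupings); applied after the
#'   automatic merge.
#' @return Object of class \code{clg_partition}: list with
#'   \code{assignment} (data.frame gene_id, chromosome, ordinal, clg),
#'   \code{segments} (the segment table with a \code{clg} column) and
#'   \code{clg_sizes} (named anchor counts, decreasing).
#' @export
merge_segments <- function(anchors, segments,
                           comparators = anchors$targets,
                           threshold = 0.75, manual_merges = NULL) {
  a <- anchors$anchors
  ns <- nrow(segments)
  # per comparator: matrix (segment x comparator chromosome) of mean indicators
  seg_of_anchor <- rep(NA_integer_, nrow(a))
  for (s in seq_len(ns)) {
    sel <- a$chromosome == segments$chromosome[s] &
      a$ordinal >= segments$start_ordinal[s] &
      a$ordinal < segments$end_ordinal[s]
    seg_of_anchor[sel] <- s
  }
  profs <- lapply(comparators, function(cmp) {
    cc <- a[[paste0("chrom.", cmp)]]
    keep <- !is.na(cc) & !is.na(seg_of_anchor)
    tab <- table(factor(seg_of_anchor[keep], levels = seq_len(ns)), cc[keep])
    m <- unclass(tab)
    sw <- sqrt(rowSums(m^2))
    sw[sw == 0] <- 1
    m / sw
  })
  # majority vote of cosine >= threshold across comparators
  adj <- matrix(FALSE, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    votes <- vapply(profs, function(m) sum(m[i, ] * m[j, ]) >= threshold,
                    logical(1))
    adj[i, j] <- adj[j, i] <- mean(votes) > 0.5
  }
  comp <- connected_components(adj)
  if (!is.null(manual_merges)) {
    for (grp in manual_merges) {
      idx <- match(grp, segments$segment_id)
      idx <- idx[!is.na(idx)]
      if (length(idx) > 1L) comp[comp %in% comp[idx]] <- comp[idx[1L]]
    }
    comp <- match(comp, unique(comp))
  }
  sizes <- tapply(segments$n_anchors, comp, sum)
  minchrom <- tapply(segments$chromosome, comp, min)
  o <- order(-sizes, minchrom)
  letters_out <- make_clg_letters(length(o))
  clg_of_comp <- stats::setNames(letters_out, names(sizes)[o])
  segments$clg <- unname(clg_of_comp[as.character(comp)])
  keep <- !is.na(seg_of_anchor)
  assignment <- data.frame(gene_id = a$outgroup_gene[keep],
                           chromosome = a$chromosome[keep],
                           ordinal = a$ordinal[keep],
                           clg = segments$clg[seg_of_anchor[keep]],
                           stringsAsFactors = FALSE)
  clg_sizes <- sort(tapply(rep(1L, nrow(assignment)), assignment$clg, sum),
                    decreasing = TRUE)
  structure(list(assignment = assignment, segments = segments,
                 clg_sizes = clg_sizes),
            class = "clg_partition")
}

#' @export
print.clg_partition <- function(x, ...) {
  cat(sprintf("clg_partition: %d linkage groups over %d anchored genes\n",
              length(x$clg_sizes), nrow(x$assignment)))
  invisible(x)
}

make_clg_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(n)]
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Assign every outgroup gene to a CLG by segment intervals
#'
#' The anchored-gene partition defines segments in ordinal coordinates; this
#' extends each chromosome's first segment to ordinal 0 and its last to the
#' chromosome end, then assigns all genes of the map (anchored or not) to
#' the CLG of their enclosing segment.  Genes on chromosomes without
#' segments stay unassigned.
#'
#' @param partition A \code{\link{merge_segments}} result.
#' @param gmap The outgroup \code{\link{gene_map}}.
#' @return data.frame \code{gene_id}, \code{chromosome}, \code{ordinal},
#'   \code{clg}.
#' @export
clg_segment_assignment <- function(partition, gmap) {
  segs <- partition$segments
  g <- gmap$genes[, c("gene_id", "chromosome", "ordinal")]
  g$clg <- NA_character_
  for (chr in unique(segs$chromosome)) {
    s <- segs[segs$chromosome == chr, , drop = FALSE]
    s <- s[order(s$start_ordinal), , drop = FALSE]
    s$start_ordinal[1L] <- 0L
    s$end_ordinal[nrow(s)] <- .Machine$integer.max
    sel <- g$chromosome == chr
    idx <- findInterval(g$ordinal[sel], s$start_ordinal)
    ok <- idx >= 1L & g$ordinal[sel] < s$end_ordinal[idx]
    g$clg[which(sel)[ok]] <- s$clg[idx[ok]]
  }
  g
}

#' Oxford dot-plot data for an anchor set
#'
#' Indices of each anchor in outgroup order versus target order, with the CLG
#' letter when a partition is supplied; suitable for external plotting.
#'
#' @param anchors An \code{\link{anchor_set}}.
#' @param target One target species.
#' @param partition Optional \code{clg_partition}.
#' @return data.frame with \code{outgroup_index}, \code{target_index},
#'   \code{outgroup_chrom}, \code{target_chrom}, \code{clg}.
#' @export
oxford_dotplot_data <- function(anchors, target, partition = NULL) {
  a <- anchors$anchors
  keep <- !is.na(a[[paste0("gene.", target)]])
  g <- a[keep, , drop = FALSE]
  o <- order(g[[paste0("chrom.", target)]], g[[paste0("ord.", target)]])
  out <- data.frame(outgroup_index = which(keep),
                    target_index = order(o),
                    outgroup_chrom = g$chromosome,
                    target_chrom = g[[paste0("chrom.", target)]],
                    stringsAsFactors = FALSE)
  out$clg <- if (!is.null(partition))
    partition$assignment$clg[match(g$outgroup_gene,
                                   partition$assignment$gene_id)]
  else NA_character_
  out
}
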