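#' Retention fractions per orthologous cell
#'
#' The retention fraction of a cell (a CLG copy in one species) is the number
#' of CLG-defining families with a member inside the cell's segments divided
#' by the number of CLG-defining genes in the outgroup.  Families are counted
#' once per chromosome (membership by segment for a/b sub-cells sharing a
#' chromosome), so tandem duplicates never raise retention; a family retained
#' on several unlinked copies counts in each, so the total retention of a CLG
#' across a species can exceed one.
#'
#' @param cells Output of \code{\link{assign_copies}}.
#' @param partition The outgroup \code{clg_partition}.
#' @param orthogroups An \code{\link{orthogroup_table}}.
#' @param ancestries Named list (per ingroup species) of
#'   \code{\link{clg_gene_ancestry}} outputs.
#' @param outgroup Outgroup species name in the orthogroup table.
#' @param outgroup_map Optional outgroup \code{\link{gene_map}}; when given,
#'   the CLG-defining denominators count every outgroup gene inside each
#'   CLG's segments (anchored or not), matching the definition of a CLG by
#'   its segment content; otherwise only anchored genes count.
#' @return data.frame of class \code{retention_table}: \code{clg},
#'   \code{cell}, \code{sublabel}, \code{species}, \code{chromosome},
#'   \code{fusion_pattern}, \code{ambiguous}, \code{numerator},
#'   \code{denominator}, \code{retention}.
#' @export
retention_fractions <- function(cells, partition, orthogroups, ancestries,
                                outgroup, outgroup_map = NULL) {
  og <- orthogroups[orthogroups$species == outgroup, , drop = FALSE]
  og$clg <- if (is.null(outgroup_map))
    partition$assignment$clg[match(og$gene_id, partition$assignment$gene_id)]
  else {
    full <- clg_segment_assignment(partition, outgroup_map)
    full$clg[match(og$gene_id, full$gene_id)]
  }
  og <- og[!is.na(og$clg), , drop = FALSE]
  denom <- table(og$clg)   # CLG-defining genes (one family member each)
  out <- cells[, c("clg", "cell", "sublabel", "species", "chromosome",
                   "fusion_pattern", "ambiguous")]
  clg_fams <- split(og$family_id, og$clg)
  out$numerator <- vapply(seq_len(nrow(cells)), function(i) {
    anc <- ancestries[[cells$species[i]]]
    sel <- anc$chromosome == cells$chromosome[i] &
      anc$ordinal >= cells$start_ordinal[i] &
      anc$ordinal < cells$end_ordinal[i] & !is.na(anc$family_id)
    fams <- unique(anc$family_id[sel])
    length(intersect(fams, clg_fams[[cells$clg[i]]]))
  }, 1L)
  out$denominator <- as.integer(denom[out$clg])
  if (any(is.na(out$denominator) | out$denominator == 0L))
    stop("zero CLG-defining gene count for some cell")
  out$retention <- out$numerator / out$denominator
  class(out) <- c("retention_table", "data.frame")
  out
}

#' Assign alpha/beta subgenome labels by paired retention
#'
#' Cells of one CLG are paired by fusion concordance (equal sets of
#' co-resident CLGs).  Within each pair the cell with the higher mean
#' retention across species is labelled alpha and the other beta; cells with
#' no concordant partner are labelled alpha-without-beta.  When a pattern
#' group holds more than two cells (e.g. four unfused copies), cells are
#' ordered by mean retention and split half/half into alpha and beta, pairing
#' the i-th alpha with the i-th beta (the pairing, not the labelling, is then
#' arbitrary and marked so).  Cells sharing a chromosome must agree in
#' subgenome; disagreements are flagged.  Copy labels 1/2 carry no retention
#' ordering: within a CLG, the alpha-beta pair with the larger total gene
#' count is copy 1.
#'
#' @param retention A \code{\link{retention_fractions}} result.
#' @return The table with added columns \code{subgenome} ("alpha", "beta" or
#'   "alpha_no_beta"), \code{pair_id}, \code{copy} (1/2),
#'   \code{pair_arbitrary}, \code{chromosome_conflict}.
#' @export
assign_alpha_beta <- function(retention) {
  ret <- as.data.frame(retention)
  # mean retention per cell across species
  ckey <- paste(ret$clg, ret$cell, sep = "\r")
  cell_mean <- tapply(ret$retention, ckey, mean)
  cell_genes <- tapply(ret$numerator, ckey, sum)
  cell_tab <- unique(ret[!ret$ambiguous, c("clg", "cell", "fusion_pattern")])
  cell_tab$mean_ret <- as.numeric(cell_mean[paste(cell_tab$clg, cell_tab$cell,
                                                  sep = "\r")])
  cell_tab$genes <- as.numeric(cell_genes[paste(cell_tab$clg, cell_tab$cell,
                                                sep = "\r")])
  cell_tab$subgenome <- "alpha_no_beta"
  cell_tab$pair_id <- NA_character_
  cell_tab$pair_arbitrary <- FALSE
  for (cl in unique(cell_tab$clg)) {
    idx_cl <- which(cell_tab$clg == cl)
    for (pat in unique(cell_tab$fusion_pattern[idx_cl])) {
      idx <- idx_cl[cell_tab$fusion_pattern[idx_cl] == pat]
      k <- length(idx)
      if (k < 2L) next
      o <- idx[order(-cell_tab$mean_ret[idx], cell_tab$cell[idx])]
      na <- ceiling(k / 2)
      alphas <- o[seq_len(na)]
      betas <- if (k > na) o[(na + 1L):k] else integer(0)
      arb <- k > 2L
      for (i in seq_along(alphas)) {
        pid <- sprintf("%s/%s/%d", cl, pat, i)
        cell_tab$subgenome[alphas[i]] <- "alpha"
        cell_tab$pair_id[alphas[i]] <- pid
        cell_tab$pair_arbitrary[alphas[i]] <- arb
        if (i <= length(betas)) {
          cell_tab$subgenome[betas[i]] <- "beta"
          cell_tab$pair_id[betas[i]] <- pid
          cell_tab$pair_arbitrary[betas[i]] <- arb
        } else {
          cell_tab$subgenome[alphas[i]] <- "alpha_no_beta"
        }
      }
    }
  }
  # copy labels per CLG, by total genes of the pair (1 = larger)
  cell_tab$copy <- NA_integer_
  for (cl in unique(cell_tab$clg)) {
    idx <- which(cell_tab$clg == cl)
    pids <- unique(stats::na.omit(cell_tab$pair_id[idx]))
    if (!length(pids)) next
    tot <- vapply(pids, function(p) sum(cell_tab$genes[idx][
      !is.na(cell_tab$pair_id[idx]) & cell_tab$pair_id[idx] == p]), numeric(1))
    rank <- stats::setNames(order(order(-tot, pids)), pids)
    cell_tab$copy[idx] <- unname(rank[cell_tab$pair_id[idx]])
  }
  m <- match(paste(ret$clg, ret$cell, sep = "\r"),
             paste(cell_tab$clg, cell_tab$cell, sep = "\r"))
  ret$subgenome <- cell_tab$subgenome[m]
  ret$pair_id <- cell_tab$pair_id[m]
  ret$copy <- cell_tab$copy[m]
  ret$pair_arbitrary <- cell_tab$pair_arbitrary[m]
  ret$subgenome[is.na(ret$subgenome)] <- "ambiguous"
  # chromosome consistency: one chromosome wholly alpha or wholly beta
  ret$chromosome_conflict <- FALSE
  key <- paste(ret$species, ret$chromosome, sep = "\r")
  for (k in unique(key)) {
    sg <- unique(ret$subgenome[key == k & ret$subgenome %in% c("alpha", "beta")])
    if (length(sg) > 1L) ret$chromosome_conflict[key == k] <- TRUE
  }
  class(ret) <- c("retention_table", "data.frame")
  ret
}

#' Extract ordered alpha-beta retention pairs
#'
#' @param retention Output of \code{\link{assign_alpha_beta}}.
#' @param species Optional subset of species to include.
#' @return data.frame \code{pair_id}, \code{species}, \code{clg},
#'   \code{alpha}, \code{beta}: one row per (pair, species) where both
#'   members were measured.  Unpaired alpha cells are excluded.
#' @export
retention_pairs <- function(retention, species = NULL) {
  r <- retention[retention$subgenome %in% c("alpha", "beta") &
                   !is.na(retention$pair_id), , drop = FALSE]
  if (!is.null(species)) r <- r[r$species %in% species, , drop = FALSE]
  key <- paste(r$pair_id, r$species, sep = "\r")
  al <- r[r$subgenome == "alpha", ]
  be <- r[r$subgenome == "beta", ]
  kal <- paste(al$pair_id, al$species, sep = "\r")
  kbe <- paste(be$pair_id, be$species, sep = "\r")
  common <- intersect(kal, kbe)
  ia <- match(common, kal); ib <- match(common, kbe)
  data.frame(pair_id = al$pair_id[ia], species = al$species[ia],
             clg = al$clg[ia], alpha = al$retention[ia],
             beta = be$retention[ib], stringsAsFactors = FALSE)
}

#' Bootstrap test of retention asymmetry against a one-class null
#'
#' Tests whether the mean difference between paired high (alpha) and low
#' (beta) retention values exceeds what is expected when retention rates are
#' drawn at random from a single class.  The null draws m pairs iid from a
#' uniform distribution on (0, c) with c twice the overall retention mean
#' (or from a normal with the observed moments), orders each pair, and
#' computes the mean (high - low); its mean and standard deviation are
#' estimated by bootstrap.  Closed forms for the uniform null are
#' E = c/3 and sd of the mean = c / sqrt(18 m).
#'
#' @param pairs data.frame with columns \code{alpha}, \code{beta} (one row
#'   per pair; per-species rows count as separate pairs) — e.g. from
#'   \code{\link{retention_pairs}}.  Unpaired cells must be excluded
#'   beforehand.
#' @param null "uniform" (default) or "normal".
#' @param reps Bootstrap replicates (default 1e6).
#' @param seed Integer seed.
#' @param c_upper Upper bound of the uniform null; default 2 x the mean of
#'   \code{all_values} (the overall retention mean).
#' @param all_values Values used to estimate the overall retention mean;
#'   defaults to all paired values.
#' @return List of class \code{asymmetry_result}: \code{observed} (mean
#'   alpha - beta), \code{null_mean}, \code{null_sd} (of the mean),
#'   \code{z}, \code{p} (one-sided upper tail), \code{c_upper}, \code{m},
#'   \code{reps}, \code{null_family}, closed-form \code{null_mean_exact},
#'   \code{null_sd_exact} (uniform only).
#' @export
asymmetry_test <- function(pairs, null = c("uniform", "normal"), reps = 1e6,
                           seed = 1L, c_upper = NULL, all_values = NULL) {
  null <- match.arg(null)
  stopifnot(is.data.frame(pairs), all(c("alpha", "beta") %in% names(pairs)))
  m <- nrow(pairs)
  if (m < 2L) stop("need at least 2 complete pairs")
  hi <- pmax(pairs$alpha, pairs$beta)
  lo <- pmin(pairs$alpha, pairs$beta)
  observed <- mean(hi - lo)
  if (is.null(all_values)) all_values <- c(pairs$alpha, pairs$beta)
  if (is.null(c_upper)) c_upper <- 2 * mean(all_values)
  mu <- mean(all_values); sdev <- stats::sd(all_values)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # bootstrap the null mean(high - low), chunked to bound memory
  tot <- 0; totsq <- 0; done <- 0
  chunk <- max(1L, min(reps, ceiling(2e6 / m)))
  while (done < reps) {
    b <- min(chunk, reps - done)
    u <- if (null == "uniform") matrix(stats::runif(2 * b * m, 0, c_upper), 2L)
         else matrix(stats::rnorm(2 * b * m, mu, sdev), 2L)
    d <- abs(u[1L, ] - u[2L, ])
    means <- colMeans(matrix(d, m))
    tot <- tot + sum(means); totsq <- totsq + sum(means^2)
    done <- done + b
  }
  null_mean <- tot / reps
  null_sd <- sqrt(max(0, totsq / reps - null_mean^2) * reps / (reps - 1))
  z <- (observed - null_mean) / null_sd
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 c_upper = c_upper, m = m, reps = reps, null_family = null,
                 null_mean_exact = if (null == "uniform") c_upper / 3 else NA,
                 null_sd_exact = if (null == "uniform")
                   c_upper / sqrt(18 * m) else NA),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(paste0("asymmetry test (%s null, c = %.4g, m = %d pairs)\n",
                     "  observed mean(high-low) = %.4f, null %.4f +/- %.4f\n",
                     "  z = %.2f, one-sided p = %.3g\n"),
              x$null_family, x$c_upper, x$m, x$observed, x$null_mean,
              x$null_sd, x$z, x$p))
  invisible(x)
}

#' Pearson correlation of retention fractions between two species
#'
#' @param retention Output of \code{\link{assign_alpha_beta}} (or
#'   \code{\link{retention_fractions}}).
#' @param sp1,sp2 Species to compare.
#' @return List: \code{r} (Pearson correlation over cells measured in both
#'   species; NA with \code{degenerate = TRUE} if either vector has zero
#'   variance), \code{n} shared cells.
#' @export
retention_correlation <- function(retention, sp1, sp2) {
  a <- retention[retention$species == sp1, ]
  b <- retention[retention$species == sp2, ]
  ka <- paste(a$clg, a$cell, a$sublabel, sep = "\r")
  kb <- paste(b$clg, b$cell, b$sublabel, sep = "\r")
  common <- intersect(ka, kb)
  if (length(common) < 3L) stop("need at least 3 shared cells")
  x <- a$retention[match(common, ka)]
  y <- b$retention[match(common, kb)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(common), degenerate = TRUE))
  list(r = stats::cor(x, y), n = length(common), degenerate = FALSE)
}

#' Permutation test of fusion-pattern concordance between subgenomes
#'
#' The statistic is the number of fused beta CLG pairs identical to a fused
#' alpha CLG pair.  Under the null, beta segments fuse at random: all perfect
#' matchings of the beta segments into pairs are equally likely.  The p-value
#' is the fraction of matchings with a statistic at least as large as
#' observed, enumerated exactly when the number of matchings
#' ((2k-1)!! for 2k segments) is at most \code{max_exact}, otherwise
#' estimated from \code{n_perm} random matchings.
#'
#' @param alpha_pairs,beta_pairs Lists (or data.frames with columns a, b) of
#'   CLG pairs fused in each subgenome; segments not fused should be omitted.
#' @param beta_segments Character vector of all beta segment labels entering
#'   the matching; defaults to the CLGs appearing in \code{beta_pairs}.
#' @param n_perm Random matchings when enumeration is infeasible.
#' @param seed Seed for the sampled case.
#' @param max_exact Enumeration limit (default 1e6 matchings).
#' @return List: \code{statistic}, \code{p}, \code{n_matchings},
#'   \code{exact}.
#' @export
fusion_concordance_test <- function(alpha_pairs, beta_pairs,
                                    beta_segments = NULL, n_perm = 1e5,
                                    seed = 1L, max_exact = 1e6) {
  norm_pairs <- function(p) {
    if (is.data.frame(p)) p <- lapply(seq_len(nrow(p)), function(i)
      c(p[[1L]][i], p[[2L]][i]))
    vapply(p, function(q) paste(sort(as.character(q)), collapse = "+"),
           character(1))
  }
  ap <- norm_pairs(alpha_pairs)
  bp <- norm_pairs(beta_pairs)
  if (is.null(beta_segments))
    beta_segments <- unlist(lapply(beta_pairs, as.character))
  beta_segments <- as.character(beta_segments)
  n <- length(beta_segments)
  if (n %% 2L) stop("perfect matching needs an even number of beta segments")
  observed <- sum(bp %in% ap)
  k <- n / 2L
  n_match <- double_factorial(n - 1L)
  stat_of <- function(perm) {   # perm: permutation of beta_segments
    pr <- vapply(seq_len(k), function(i)
      paste(sort(perm[c(2L * i - 1L, 2L * i)]), collapse = "+"), character(1))
    sum(pr %in% ap)
  }
  if (n_match <= max_exact) {
    cnt <- count_matchings_geq(beta_segments, ap, observed)
    return(list(statistic = observed, p = cnt / n_match,
                n_matchings = n_match, exact = TRUE))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  hits <- sum(vapply(seq_len(n_perm), function(i)
    stat_of(sample(beta_segments)) >= observed, logical(1)))
  list(statistic = observed, p = (hits + 1) / (n_perm + 1),
       n_matchings = n_match, exact = FALSE)
}

double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# recursive enumeration of perfect matchings, counting those with
# concordance >= threshold; prunes when even all-remaining-concordant
# cannot reach the threshold
count_matchings_geq <- function(items, alpha_keys, threshold) {
  recurse <- function(items, acc) {
    n <- length(items)
    if (!n) return(if (acc >= threshold) 1 else 0)
    if (acc + n / 2 < threshold) return(0)
    first <- items[1L]
    rest <- items[-1L]
    total <- 0
    for (j in seq_along(rest)) {
      key <- paste(sort(c(first, rest[j])), collapse = "+")
      total <- total + recurse(rest[-j], acc + (key %in% alpha_keys))
    }
    total
  }
  recurse(items, 0)
}

# seed handling: set a temporary seed, restoring the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
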