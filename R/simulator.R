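#' Simulation configuration
#'
#' Encodes the two-round genome-duplication scenario used to generate
#' synthetic multi-species gene maps with known truth: an ancestral genome of
#' \code{n_clgs} linkage groups; an unduplicated outgroup lineage that
#' accumulates within-chromosome inversions plus a few fusions with sharp
#' junctions; and an ingroup stem that undergoes autotetraploidy (1R,
#' symmetric per-copy retention), a series of chromosome fusions with local
#' junction mixing, then allotetraploidy (2R) in which the two subgenomes
#' diverge and lose genes asymmetrically (retention defaults 0.39 for alpha
#' and 0.15 for beta).  Loss is applied once on the stem (so descendant
#' species share it) and each terminal lineage adds light independent loss
#' and rearrangement.
#'
#' @param n_clgs Number of ancestral linkage groups (default 17).
#' @param genes_per_clg Mean genes per linkage group (Poisson, default 300).
#' @param outgroup_fusions Fusions on the outgroup lineage (default 3).
#' @param outgroup_inversions Within-chromosome inversions per outgroup
#'   chromosome before fusion (default 30).
#' @param outgroup_mixing Junction-spanning inversions per outgroup fusion
#'   (default 0: sharp boundaries).
#' @param wgd1_retention Per-copy retention probability at 1R (symmetric by
#'   construction; default 1 so that the configured 2R rates equal end-state
#'   cell retentions).
#' @param stem_inversions Inversions per chromosome on the ingroup stem
#'   before 1R.
#' @param stem_fusions Fusions on the ingroup stem between 1R and 2R.
#' @param stem_fusions_distinct When TRUE (default), each linkage group
#'   joins at most one stem fusion, so every group keeps an unfused copy and
#'   remains identifiable from synteny (as in the study system, where every
#'   ancestral group survives unfused in at least one descendant).
#' @param stem_mixing Junction-spanning inversions per stem fusion.
#' @param wgd2_retention Named vector c(alpha=, beta=) of per-subgenome
#'   retention probabilities at 2R.
#' @param divergence_inversions Independent inversions per chromosome per
#'   subgenome at 2R (progenitor divergence).
#' @param terminal_loss Per-gene independent loss probability on each
#'   terminal lineage (last family copy in a species is protected).
#' @param terminal_inversions Inversions per chromosome per terminal.
#' @param inversion_span Maximal span (genes) of divergence and terminal
#'   inversions; bounded so that accumulated local rearrangements scramble
#'   gene order without dissolving macro-scale ancestry blocks.
#' @param terminal_translocations Random block translocations per terminal.
#' @param ingroup_species Names of the post-2R lineages (>= 2).
#' @param min_retained_copies Minimum surviving copies per family at each
#'   loss event (default 0: a family may lose every duplicated copy, as the
#'   outgroup still defines it).
#' @param score_noise Standard deviation of the per-gene divergence
#'   subtracted from the maximal similarity score of 100.
#' @param background_hits Number of random non-orthologous similarity hits
#'   per species pair.
#' @param seed Integer seed.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_clgs = 17L, genes_per_clg = 300,
                              outgroup_fusions = 3L,
                              outgroup_inversions = 30L,
                              outgroup_mixing = 0L,
                              wgd1_retention = 1,
                              stem_inversions = 10L,
                              stem_fusions = 6L, stem_mixing = 2L,
                              stem_fusions_distinct = TRUE,
                              wgd2_retention = c(alpha = 0.39, beta = 0.15),
                              divergence_inversions = 10L,
                              terminal_loss = 0.03,
                              terminal_inversions = 10L,
                              inversion_span = 40L,
                              terminal_translocations = 0L,
                              ingroup_species = c("gar", "chick", "frog"),
                              min_retained_copies = 0L,
                              score_noise = 5,
                              background_hits = 2000L,
                              seed = 1L) {
  stopifnot(n_clgs >= 1, genes_per_clg >= 1, wgd1_retention >= 0,
            wgd1_retention <= 1, all(wgd2_retention >= 0),
            all(wgd2_retention <= 1), length(ingroup_species) >= 1,
            terminal_loss >= 0, terminal_loss < 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Scramble a gene order by random inversions
#'
#' @param ids Character vector (a chromosome's gene order).
#' @param n_inversions Number of random-interval reversals.
#' @param span Maximal inversion length in genes (default unbounded);
#'   bounded spans scramble local order while preserving macro-scale block
#'   structure.
#' @return The scrambled order; gene content is unchanged.
#' @export
scramble <- function(ids, n_inversions, span = Inf) {
  n <- length(ids)
  if (n < 2L || n_inversions < 1L) return(ids)
  for (r in seq_len(n_inversions)) {
    if (is.finite(span) && span < n) {
      len <- sample.int(min(span, n), 1L)
      a <- sample.int(n - len + 1L, 1L)
      ab <- c(a, a + len - 1L)
    } else ab <- sort(sample.int(n, 2L))
    ids[ab[1L]:ab[2L]] <- ids[ab[2L]:ab[1L]]
  }
  ids
}

#' Fuse two chromosomes and mix across the junction
#'
#' Concatenates two gene orders and applies junction-spanning inversions.
#' With zero mixing the boundary stays sharp; with mixing both ancestries
#' interleave near the junction.
#'
#' @param a_ids,b_ids Gene orders of the two chromosomes.
#' @param mixing_inversions Number of inversions spanning the junction.
#' @param span Maximal extent of mixing on either side (genes, default 50).
#' @return List: \code{order} (fused gene order) and \code{junction}
#'   (0-based ordinal of the first gene of \code{b_ids} before mixing).
#' @export
fuse_and_mix <- function(a_ids, b_ids, mixing_inversions = 0L, span = 50L) {
  ids <- c(a_ids, b_ids)
  j <- length(a_ids)
  n <- length(ids)
  if (mixing_inversions > 0L && j >= 1L && j < n) {
    for (r in seq_len(mixing_inversions)) {
      lo <- sample(max(1L, j - span + 1L):j, 1L)
      hi <- sample((j + 1L):min(n, j + span), 1L)
      ids[lo:hi] <- ids[hi:lo]
    }
  }
  list(order = ids, junction = j)
}

#' Whole-genome duplication with per-copy loss
#'
#' Duplicates every chromosome, labels the two copies, optionally scrambles
#' each copy independently (divergence), and applies per-family per-copy
#' Bernoulli retention.  Families losing all copies are redrawn conditional
#' on at least \code{min_retained} survivors (with all-zero rates the
#' survivors are chosen uniformly), so configured rates stay close to the
#' realized per-copy marginals.
#'
#' @param genome data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{pos}, \code{family_id} (and any label columns).
#' @param mode "auto" (one shared retention rate) or "allo" (per-subgenome
#'   rates, applied after independent divergence scrambling).
#' @param retention For auto a single rate; for allo a length-2 vector
#'   (first = alpha, second = beta).
#' @param label_field Column recording the new copy label.
#' @param labels Length-2 labels for the copies.
#' @param divergence_inversions Inversions per chromosome per copy before
#'   loss (allo).
#' @param inversion_span Maximal span of divergence inversions.
#' @param min_retained Minimum surviving copies per family (0 disables the
#'   constraint).
#' @return The duplicated genome data.frame; gene ids gain a label suffix,
#'   chromosomes gain a \code{-<label>} suffix.
#' @export
apply_wgd <- function(genome, mode = c("auto", "allo"), retention,
                      label_field, labels, divergence_inversions = 0L,
                      inversion_span = Inf, min_retained = 0L) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    stopifnot(length(retention) <= 2)
    if (length(retention) == 2 && retention[1L] != retention[2L])
      stop("autotetraploid copies must share one retention rate")
    retention <- rep(retention[1L], 2L)
  } else stopifnot(length(retention) == 2)
  copies <- lapply(1:2, function(k) {
    g <- genome
    g$chromosome <- paste0(g$chromosome, "-", labels[k])
    g$gene_id <- paste0(g$gene_id, labels[k])
    g[[label_field]] <- labels[k]
    g$.rate <- retention[k]
    g
  })
  dup <- rbind(copies[[1L]], copies[[2L]])
  if (divergence_inversions > 0L)
    dup <- scramble_genome(dup, divergence_inversions, inversion_span)
  keep <- stats::runif(nrow(dup)) < dup$.rate
  # respect min-retained-copies by conditional redraw per family
  fams <- if (min_retained > 0L) split(seq_len(nrow(dup)), dup$family_id)
          else list()
  for (idx in fams) {
    if (sum(keep[idx]) >= min_retained) next
    if (all(dup$.rate[idx] == 0)) {
      k2 <- rep(FALSE, length(idx))
      k2[sample.int(length(idx), min_retained)] <- TRUE
    } else {
      repeat {
        k2 <- stats::runif(length(idx)) < dup$.rate[idx]
        if (sum(k2) >= min_retained) break
      }
    }
    keep[idx] <- k2
  }
  dup <- dup[keep, , drop = FALSE]
  dup$.rate <- NULL
  renumber_positions(dup)
}

# apply n_inv inversions to each chromosome of a genome data.frame
scramble_genome <- function(genome, n_inv, span = Inf) {
  genome <- genome[order(genome$chromosome, genome$pos), , drop = FALSE]
  out <- lapply(split(genome, genome$chromosome), function(g) {
    g[match(scramble(g$gene_id, n_inv, span), g$gene_id), , drop = FALSE]
  })
  renumber_positions(do.call(rbind, out))
}

renumber_positions <- function(genome) {
  genome <- genome[order(genome$chromosome), , drop = FALSE]
  genome$pos <- stats::ave(seq_len(nrow(genome)), genome$chromosome,
                           FUN = seq_along)
  rownames(genome) <- NULL
  genome
}

# fuse n random pairs of distinct chromosomes; returns genome + junction log.
# with distinct_units, the base linkage groups entering fusions must all
# differ, so each group keeps an unfused copy
fuse_genome <- function(genome, n_fusions, mixing, what,
                        distinct_units = FALSE) {
  junctions <- list()
  used_units <- character(0)
  unit_of <- function(chrom) unique(sub("-[0-9]+$", "", sub("f+$", "", chrom)))
  for (f in seq_len(n_fusions)) {
    chroms <- unique(genome$chromosome)
    if (length(chroms) < 2L)
      stop("configuration demands more fusions than available chromosomes")
    pair <- sample(chroms, 2L)
    if (distinct_units) {
      ok <- FALSE
      for (try in 1:1000) {
        units <- c(unit_of(pair[1L]), unit_of(pair[2L]))
        if (!anyDuplicated(units) && !any(units %in% used_units)) {
          ok <- TRUE; break
        }
        pair <- sample(chroms, 2L)
      }
      if (!ok)
        stop("configuration demands more fusions than available chromosomes")
      used_units <- c(used_units, unit_of(pair[1L]), unit_of(pair[2L]))
    }
    a <- genome[genome$chromosome == pair[1L], , drop = FALSE]
    a <- a[order(a$pos), ]
    b <- genome[genome$chromosome == pair[2L], , drop = FALSE]
    b <- b[order(b$pos), ]
    fused <- fuse_and_mix(a$gene_id, b$gene_id, mixing)
    newname <- paste0(pair[1L], "f")
    # keep earlier junction records valid on the renamed chromosome: the
    # left partner keeps its ordinals, the right partner's shift by |left|
    junctions <- lapply(junctions, function(jn) {
      if (jn$chromosome == pair[1L]) jn$chromosome <- newname
      else if (jn$chromosome == pair[2L]) {
        jn$chromosome <- newname
        jn$junction <- jn$junction + nrow(a)
      }
      jn
    })
    keep <- genome[!genome$chromosome %in% pair, , drop = FALSE]
    merged <- rbind(a, b)
    merged <- merged[match(fused$order, merged$gene_id), ]
    merged$chromosome <- newname
    merged$pos <- seq_len(nrow(merged))
    genome <- rbind(keep, merged)
    junctions[[f]] <- data.frame(event = what, chromosome = newname,
                                 junction = fused$junction,
                                 left = pair[1L], right = pair[2L],
                                 stringsAsFactors = FALSE)
  }
  list(genome = renumber_positions(genome), junctions = junctions)
}

#' Simulate multi-species gene maps under the two-duplication scenario
#'
#' Runs the full scenario of \code{\link{simulation_config}} and emits gene
#' maps, similarity tables (outgroup vs each ingroup, both directions), the
#' orthogroup (true family) table, and complete truth labels.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List of class \code{simulated_dataset}:
#'   \item{gene_maps}{named list of \code{\link{gene_map}}s (outgroup +
#'     ingroups)}
#'   \item{similarity}{named list per ingroup with elements \code{fwd}
#'     (outgroup to ingroup) and \code{rev}}
#'   \item{orthogroups}{\code{\link{orthogroup_table}}}
#'   \item{truth}{list: \code{genes} (per-species truth labels),
#'     \code{outgroup_junctions}, \code{stem_fusions} (CLG-copy pairs fused
#'     before 2R), \code{events} (event log)}
#'   \item{config}{the configuration}
#' @export
simulate_genomes <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  events <- list()
  log_event <- function(lineage, type, ...)
    events[[length(events) + 1L]] <<- c(list(lineage = lineage, type = type),
                                        list(...))
  # ancestral genome: one chromosome per linkage group
  sizes <- pmax(40L, stats::rpois(config$n_clgs, config$genes_per_clg))
  clg_names <- sprintf("CLG%02d", seq_len(config$n_clgs))
  ancestor <- do.call(rbind, lapply(seq_len(config$n_clgs), function(i) {
    data.frame(gene_id = sprintf("%s_F%04d", clg_names[i], seq_len(sizes[i])),
               chromosome = clg_names[i], pos = seq_len(sizes[i]),
               family_id = sprintf("%s_F%04d", clg_names[i],
                                   seq_len(sizes[i])),
               clg = clg_names[i], copy = "0", subgenome = "0",
               stringsAsFactors = FALSE)
  }))
  log_event("root", "ancestor", n_clgs = config$n_clgs, sizes = sizes)

  # outgroup lineage: scramble within chromosomes, then fuse sharply
  outg <- scramble_genome(ancestor, config$outgroup_inversions)
  log_event("outgroup", "inversions", per_chrom = config$outgroup_inversions)
  fo <- fuse_genome(outg, config$outgroup_fusions, config$outgroup_mixing,
                    "outgroup_fusion")
  outg <- fo$genome
  outgroup_junctions <- rbind(empty_junctions(), do.call(rbind, fo$junctions))
  for (j in fo$junctions)
    log_event("outgroup", "fusion", chromosome = j$chromosome,
              junction = j$junction, left = j$left, right = j$right)
  outg$gene_id <- paste0("out_", outg$gene_id)

  # ingroup stem: scramble, 1R auto, fusions with mixing, 2R allo
  stem <- scramble_genome(ancestor, config$stem_inversions)
  stem <- apply_wgd(stem, "auto", config$wgd1_retention,
                    label_field = "copy", labels = c("1", "2"),
                    min_retained = config$min_retained_copies)
  log_event("stem", "wgd_auto", retention = config$wgd1_retention)
  fs <- fuse_genome(stem, config$stem_fusions, config$stem_mixing,
                    "stem_fusion",
                    distinct_units = isTRUE(config$stem_fusions_distinct))
  stem <- fs$genome
  stem_fusions <- rbind(empty_junctions(), do.call(rbind, fs$junctions))
  for (j in fs$junctions)
    log_event("stem", "fusion", chromosome = j$chromosome,
              junction = j$junction, left = j$left, right = j$right)
  stem <- apply_wgd(stem, "allo", unname(config$wgd2_retention),
                    label_field = "subgenome", labels = c("alpha", "beta"),
                    divergence_inversions = config$divergence_inversions,
                    inversion_span = config$inversion_span,
                    min_retained = config$min_retained_copies)
  log_event("stem", "wgd_allo", retention = config$wgd2_retention)

  # terminal lineages: independent light loss (last copy protected),
  # inversions, optional translocations
  terminals <- lapply(config$ingroup_species, function(sp) {
    g <- stem
    g$gene_id <- paste0(sp, "_", g$gene_id)
    if (config$terminal_loss > 0) {
      drop <- stats::runif(nrow(g)) < config$terminal_loss
      nfam <- stats::ave(as.integer(!drop), g$family_id, FUN = sum)
      drop[nfam == 0L] <- FALSE   # protect the family's last copy
      g <- g[!drop, , drop = FALSE]
    }
    g <- scramble_genome(g, config$terminal_inversions,
                         config$inversion_span)
    if (config$terminal_translocations > 0L)
      for (tr in seq_len(config$terminal_translocations))
        g <- translocate_block(g)
    log_event(sp, "terminal", loss = config$terminal_loss,
              inversions = config$terminal_inversions)
    renumber_positions(g)
  })
  names(terminals) <- config$ingroup_species

  gene_maps <- c(list(outgroup = genome_to_map("outgroup", outg)),
                 lapply(config$ingroup_species, function(sp)
                   genome_to_map(sp, terminals[[sp]])))
  names(gene_maps) <- c("outgroup", config$ingroup_species)

  # similarity: per ingroup gene a divergence from the ancestral protein;
  # the family member with the smallest divergence is the mutual best hit
  similarity <- lapply(config$ingroup_species, function(sp) {
    tg <- terminals[[sp]]
    div <- abs(stats::rnorm(nrow(tg), 0, config$score_noise)) +
      stats::runif(nrow(tg), 0, 1e-3)  # a.s. unique scores
    fam_out <- stats::setNames(outg$gene_id, outg$family_id)
    hit_out <- fam_out[tg$family_id]
    ok <- !is.na(hit_out)
    hits <- data.frame(query = hit_out[ok], subject = tg$gene_id[ok],
                       score = 100 - div[ok], stringsAsFactors = FALSE)
    if (config$background_hits > 0L) {
      qi <- sample.int(nrow(outg), config$background_hits, replace = TRUE)
      si <- sample.int(nrow(tg), config$background_hits, replace = TRUE)
      bg <- data.frame(query = outg$gene_id[qi], subject = tg$gene_id[si],
                       score = stats::runif(config$background_hits, 10, 40),
                       stringsAsFactors = FALSE)
      bg <- bg[outg$family_id[qi] != tg$family_id[si], , drop = FALSE]
      hits <- rbind(hits, bg)
    }
    list(fwd = similarity_table("outgroup", sp, hits),
         rev = similarity_table(sp, "outgroup",
                                data.frame(query = hits$subject,
                                           subject = hits$query,
                                           score = hits$score,
                                           stringsAsFactors = FALSE)))
  })
  names(similarity) <- config$ingroup_species

  fam_rows <- rbind(
    data.frame(family_id = outg$family_id, species = "outgroup",
               gene_id = outg$gene_id, stringsAsFactors = FALSE),
    do.call(rbind, lapply(config$ingroup_species, function(sp)
      data.frame(family_id = terminals[[sp]]$family_id, species = sp,
                 gene_id = terminals[[sp]]$gene_id,
                 stringsAsFactors = FALSE))))
  truth_genes <- rbind(
    cbind(species = "outgroup", outg),
    do.call(rbind, lapply(config$ingroup_species, function(sp)
      cbind(species = sp, terminals[[sp]]))))
  rownames(truth_genes) <- NULL
  structure(list(gene_maps = gene_maps, similarity = similarity,
                 orthogroups = orthogroup_table(fam_rows),
                 truth = list(genes = truth_genes,
                              outgroup_junctions = outgroup_junctions,
                              stem_fusions = stem_fusions,
                              events = events),
                 config = config),
            class = "simulated_dataset")
}

empty_junctions <- function() {
  data.frame(event = character(), chromosome = character(),
             junction = integer(), left = character(), right = character(),
             stringsAsFactors = FALSE)
}

genome_to_map <- function(species, genome) {
  gene_map(species,
           data.frame(gene_id = genome$gene_id,
                      chromosome = genome$chromosome,
                      bp_start = 1000 * genome$pos,
                      bp_end = 1000 * genome$pos + 500,
                      stringsAsFactors = FALSE))
}

# move a random block of up to 30 genes to another chromosome's end
translocate_block <- function(genome) {
  chroms <- unique(genome$chromosome)
  if (length(chroms) < 2L) return(genome)
  from <- sample(chroms, 1L)
  to <- sample(setdiff(chroms, from), 1L)
  g <- genome[genome$chromosome == from, , drop = FALSE]
  g <- g[order(g$pos), ]
  len <- min(nrow(g) - 1L, sample(5:30, 1L))
  if (len < 1L) return(genome)
  start <- sample.int(nrow(g) - len + 1L, 1L)
  idx <- start:(start + len - 1L)
  moved <- g$gene_id[idx]
  genome$chromosome[genome$gene_id %in% moved] <- to
  genome$pos[genome$gene_id %in% moved] <-
    max(genome$pos[genome$chromosome == to]) + seq_along(moved)
  renumber_positions(genome)
}

#' Write a simulated dataset to a directory
#'
#' Gene maps as 4-column TSVs, similarity tables as 3-column TSVs,
#' orthogroups and truth labels as TSVs, the event log as JSON — the exact
#' dialects the readers of this package accept.
#'
#' @param dataset A \code{\link{simulate_genomes}} result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(dataset$gene_maps))
    write_gene_map(dataset$gene_maps[[sp]],
                   file.path(dir, paste0("genemap_", sp, ".tsv")))
  for (sp in names(dataset$similarity)) {
    write_tsv(dataset$similarity[[sp]]$fwd$hits,
              file.path(dir, paste0("similarity_outgroup_", sp, ".tsv")))
    write_tsv(dataset$similarity[[sp]]$rev$hits,
              file.path(dir, paste0("similarity_", sp, "_outgroup.tsv")))
  }
  write_tsv(as.data.frame(dataset$orthogroups),
            file.path(dir, "orthogroups.tsv"))
  write_tsv(dataset$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(dataset$truth$outgroup_junctions,
            file.path(dir, "truth_outgroup_junctions.tsv"))
  write_tsv(dataset$truth$stem_fusions, file.path(dir, "truth_stem_fusions.tsv"))
  jsonlite::write_json(dataset$truth$events, file.path(dir, "events.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated (or equivalently formatted) dataset from a directory
#'
#' @param dir Directory written by \code{\link{write_dataset}}.
#' @return List with \code{gene_maps}, \code{similarity} and
#'   \code{orthogroups} (truth files, when present, under \code{truth}).
#' @export
read_dataset <- function(dir) {
  gm_files <- list.files(dir, "^genemap_.*\\.tsv$", full.names = TRUE)
  species <- sub("^genemap_(.*)\\.tsv$", "\\1", basename(gm_files))
  gene_maps <- lapply(gm_files, read_gene_map, format = "tsv")
  names(gene_maps) <- vapply(gene_maps, function(g) g$species, character(1))
  ing <- setdiff(names(gene_maps), "outgroup")
  similarity <- lapply(ing, function(sp) {
    fwd <- file.path(dir, paste0("similarity_outgroup_", sp, ".tsv"))
    rev <- file.path(dir, paste0("similarity_", sp, "_outgroup.tsv"))
    if (!file.exists(fwd)) return(NULL)
    list(fwd = read_similarity_with_header(fwd, "outgroup", sp),
         rev = read_similarity_with_header(rev, sp, "outgroup"))
  })
  names(similarity) <- ing
  similarity <- similarity[!vapply(similarity, is.null, logical(1))]
  og_path <- file.path(dir, "orthogroups.tsv")
  orthogroups <- if (file.exists(og_path)) read_orthogroups(og_path) else NULL
  truth <- NULL
  tg <- file.path(dir, "truth_genes.tsv")
  if (file.exists(tg))
    truth <- list(genes = read_tsv(tg),
                  outgroup_junctions =
                    read_tsv(file.path(dir, "truth_outgroup_junctions.tsv")),
                  stem_fusions =
                    read_tsv(file.path(dir, "truth_stem_fusions.tsv")))
  list(gene_maps = gene_maps, similarity = similarity,
       orthogroups = orthogroups, truth = truth)
}

read_similarity_with_header <- function(path, from, to) {
  tab <- read_tsv(path)
  similarity_table(from, to, tab[, c("query", "subject", "score")])
}
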