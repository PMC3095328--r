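## Microsynteny analysis between two annotated regions: reciprocal-best
## orthologue pairing from a protein-homology table, tandem-duplication
## collapsing, block detection tolerant of local rearrangement, and the
## relative syntenic quality statistic
##
##   quality = 100 * (conserved_A + conserved_B) / (total_A + total_B)
##
## computed after excluding transposable elements and counting each
## tandem array of mutually homologous adjacent genes as one gene.

## rows of the homology table passing the cut-offs
filter_homology <- function(homology, evalue_cut, identity_floor) {
  homology[homology$evalue <= evalue_cut &
           homology$identity >= identity_floor, , drop = FALSE]
}

#' Pair orthologues between two gene sets
#'
#' Reciprocal-best pairing: for each gene the best partner is chosen by
#' e-value (ties broken by identity), and a pair is kept only when the
#' choice is mutual. TE-flagged genes are excluded before pairing.
#'
#' @param genes_a,genes_b `gene_models` data.frames for the two regions.
#' @param homology data.frame `gene_a`, `gene_b`, `identity`, `evalue`
#'   (gene_a from region A, gene_b from region B).
#' @param evalue_cut maximum e-value (default 1e-46).
#' @param identity_floor minimum percent identity (default 0).
#' @return data.frame of pairs `gene_a`, `gene_b`, `identity`, `evalue`.
#' @export
pair_homologs <- function(genes_a, genes_b, homology,
                          evalue_cut = 1e-46, identity_floor = 0) {
  a_ok <- genes_a$gene_id[!genes_a$te_flag]
  b_ok <- genes_b$gene_id[!genes_b$te_flag]
  h <- filter_homology(homology, evalue_cut, identity_floor)
  h <- h[h$gene_a %in% a_ok & h$gene_b %in% b_ok, , drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), evalue = numeric()))
  }
  h <- h[order(h$evalue, -h$identity), , drop = FALSE]
  best_a <- h[!duplicated(h$gene_a), , drop = FALSE]   # best partner per a
  best_b <- h[!duplicated(h$gene_b), , drop = FALSE]   # best partner per b
  key_a <- paste(best_a$gene_a, best_a$gene_b)
  key_b <- paste(best_b$gene_a, best_b$gene_b)
  res <- best_a[key_a %in% key_b, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse tandem duplications
#'
#' Maximal runs of adjacent same-region non-TE genes that are mutually
#' homologous (a pairwise hit in the homology table at the same cuts)
#' collapse to one representative: the first member carrying a
#' cross-region pair, else the first member. TE rows pass through
#' untouched.
#'
#' @param genes a `gene_models` data.frame, one region.
#' @param homology homology table; same-region rows are used to detect
#'   tandem arrays (either column order).
#' @param pairs optional cross-region pairs from [pair_homologs()], used
#'   to choose representatives.
#' @param evalue_cut,identity_floor cut-offs applied to the same-region
#'   rows.
#' @return data.frame with the collapsed gene list and an `array_size`
#'   column (1 for genes not in an array).
#' @export
collapse_tandem <- function(genes, homology, pairs = NULL,
                            evalue_cut = 1e-46, identity_floor = 0) {
  g <- genes[order(genes$start), , drop = FALSE]
  h <- filter_homology(homology, evalue_cut, identity_floor)
  linked <- function(x, y) {
    any((h$gene_a == x & h$gene_b == y) | (h$gene_a == y & h$gene_b == x))
  }
  paired_ids <- if (is.null(pairs)) character(0) else
    c(pairs$gene_a, pairs$gene_b)
  nonte <- which(!g$te_flag)
  ## group adjacent (among non-TE genes) mutually homologous genes
  grp <- integer(nrow(g))
  gid <- 0L
  prev <- 0L
  for (i in nonte) {
    if (prev == 0L || !linked(g$gene_id[prev], g$gene_id[i])) gid <- gid + 1L
    grp[i] <- gid
    prev <- i
  }
  grp[g$te_flag] <- -seq_len(sum(g$te_flag))   # TEs: own singleton groups
  keep <- integer(0)
  sizes <- integer(0)
  for (u in unique(grp)) {
    idx <- which(grp == u)
    rep_idx <- idx[1]
    with_pair <- idx[g$gene_id[idx] %in% paired_ids]
    if (length(with_pair)) rep_idx <- with_pair[1]
    keep <- c(keep, rep_idx)
    sizes <- c(sizes, length(idx))
  }
  ord <- order(keep)
  out <- g[keep[ord], , drop = FALSE]
  out$array_size <- sizes[ord]
  rownames(out) <- NULL
  out
}

#' Find syntenic blocks
#'
#' Blocks are maximal runs of orthologue pairs in which consecutive
#' paired genes are separated by at most `max_gap` unpaired genes on
#' both regions, irrespective of orientation and exact gene order within
#' the run. Runs with a single pair are discarded.
#'
#' @param genes_a,genes_b `gene_models` data.frames (position-sorted
#'   internally).
#' @param pairs pairs from [pair_homologs()].
#' @param max_gap maximum unpaired genes between consecutive pairs
#'   (default 3).
#' @return list of blocks; each block is a list with `pairs`,
#'   `a_genes`/`b_genes` (gene_id vectors of every gene inside the block
#'   span, unpaired and TE genes included) and `a_range`/`b_range`.
#' @export
find_blocks <- function(genes_a, genes_b, pairs, max_gap = 3L) {
  ga <- genes_a[order(genes_a$start), , drop = FALSE]
  gb <- genes_b[order(genes_b$start), , drop = FALSE]
  if (nrow(pairs) == 0) return(list())
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  stopifnot(!anyNA(ia), !anyNA(ib))
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]; pr <- pairs[ord, , drop = FALSE]
  ## TE-flagged entries neither pair nor count as interruptions (they
  ## are excluded from the statistic, so they do not break contiguity)
  paired_a <- seq_len(nrow(ga)) %in% ia | ga$te_flag
  paired_b <- seq_len(nrow(gb)) %in% ib | gb$te_flag
  ## unpaired genes strictly between two indices
  gap_between <- function(paired, i, j) {
    lo <- min(i, j) + 1L; hi <- max(i, j) - 1L
    if (lo > hi) 0L else sum(!paired[lo:hi])
  }
  blocks <- list()
  cur <- 1L
  start <- 1L
  while (cur <= length(ia)) {
    nxt <- cur + 1L
    while (nxt <= length(ia) &&
           gap_between(paired_a, ia[nxt - 1L], ia[nxt]) <= max_gap &&
           gap_between(paired_b, ib[nxt - 1L], ib[nxt]) <= max_gap) {
      nxt <- nxt + 1L
    }
    if (nxt - start >= 2L) {
      sel <- start:(nxt - 1L)
      a_lo <- min(ia[sel]); a_hi <- max(ia[sel])
      b_lo <- min(ib[sel]); b_hi <- max(ib[sel])
      blocks[[length(blocks) + 1L]] <- list(
        pairs = pr[sel, , drop = FALSE],
        a_genes = ga$gene_id[a_lo:a_hi],
        b_genes = gb$gene_id[b_lo:b_hi],
        a_range = c(ga$start[a_lo], ga$end[a_hi]),
        b_range = c(gb$start[b_lo], gb$end[b_hi]))
    }
    cur <- nxt
    start <- nxt
  }
  blocks
}

#' Relative syntenic quality of a block
#'
#' `100 * (conserved_A + conserved_B) / (total_A + total_B)` where each
#' side's totals count non-TE genes inside the block span after
#' collapsing tandem duplications, and a collapsed entry is conserved
#' when any member of its array has a cross-region pair. One decimal,
#' rounded half-up.
#'
#' @param block one block from [find_blocks()].
#' @param genes_a,genes_b full `gene_models` data.frames.
#' @param homology homology table (same-region rows drive tandem
#'   collapsing).
#' @param evalue_cut,identity_floor cut-offs (defaults 1e-46, 0).
#' @return list with `quality` plus the post-collapse counts
#'   `conserved_a`, `conserved_b`, `total_a`, `total_b`.
#' @export
synteny_quality <- function(block, genes_a, genes_b, homology,
                            evalue_cut = 1e-46, identity_floor = 0) {
  count_side <- function(genes, ids, pair_ids) {
    sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    coll <- collapse_tandem(sub, homology, evalue_cut = evalue_cut,
                            identity_floor = identity_floor)
    ## conserved: any member of the (possibly collapsed) array is paired
    conserved <- 0L
    g <- sub[order(sub$start), , drop = FALSE]
    kept <- coll[!coll$te_flag, , drop = FALSE]
    for (i in seq_len(nrow(kept))) {
      members <- array_members(g, kept$gene_id[i], kept$array_size[i],
                               homology, evalue_cut, identity_floor)
      if (any(members %in% pair_ids)) conserved <- conserved + 1L
    }
    list(total = nrow(kept), conserved = conserved)
  }
  pair_ids <- c(block$pairs$gene_a, block$pairs$gene_b)
  a <- count_side(genes_a, block$a_genes, pair_ids)
  b <- count_side(genes_b, block$b_genes, pair_ids)
  denom <- a$total + b$total
  if (denom == 0) stop("block contains no countable genes", call. = FALSE)
  list(quality = round_half_up(100 * (a$conserved + b$conserved) / denom, 1),
       conserved_a = a$conserved, conserved_b = b$conserved,
       total_a = a$total, total_b = b$total)
}

## recover the member ids of the tandem array represented by `rep_id`
array_members <- function(sorted_genes, rep_id, size, homology,
                          evalue_cut, identity_floor) {
  if (size == 1L) return(rep_id)
  h <- filter_homology(homology, evalue_cut, identity_floor)
  linked <- function(x, y) {
    any((h$gene_a == x & h$gene_b == y) | (h$gene_a == y & h$gene_b == x))
  }
  nonte <- sorted_genes[!sorted_genes$te_flag, , drop = FALSE]
  i <- match(rep_id, nonte$gene_id)
  members <- rep_id
  j <- i
  while (j > 1L && linked(nonte$gene_id[j - 1L], nonte$gene_id[j])) {
    j <- j - 1L; members <- c(nonte$gene_id[j], members)
  }
  j <- i
  while (j < nrow(nonte) && linked(nonte$gene_id[j], nonte$gene_id[j + 1L])) {
    j <- j + 1L; members <- c(members, nonte$gene_id[j])
  }
  members
}

#' Structural ratios of orthologue pairs
#'
#' Mean of per-pair ratios (region A over region B) for protein length,
#' exon count and mean intron length, reported to two decimals. Pairs
#' lacking the required structural data are excluded with a warning;
#' intronless pairs do not enter the intron ratio.
#'
#' @param pairs pairs from [pair_homologs()].
#' @param genes_a,genes_b `gene_models` data.frames.
#' @return list with `protein_length_ratio`, `exon_count_ratio`,
#'   `mean_intron_ratio` and `n_pairs`.
#' @export
ratio_stats <- function(pairs, genes_a, genes_b) {
  pl <- ec <- il <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- genes_a[genes_a$gene_id == pairs$gene_a[i], , drop = FALSE]
    b <- genes_b[genes_b$gene_id == pairs$gene_b[i], , drop = FALSE]
    if (nrow(a) != 1 || nrow(b) != 1 ||
        is.na(a$protein_length) || is.na(b$protein_length)) {
      dropped <- dropped + 1L
      next
    }
    pl <- c(pl, a$protein_length / b$protein_length)
    ec <- c(ec, nrow(a$exons[[1]]) / nrow(b$exons[[1]]))
    ia <- intron_lengths(a$exons[[1]])
    ib <- intron_lengths(b$exons[[1]])
    if (length(ia) && length(ib)) il <- c(il, mean(ia) / mean(ib))
  }
  if (dropped) warning(dropped, " pair(s) lacked structural data")
  list(protein_length_ratio = round_half_up(mean(pl), 2),
       exon_count_ratio = round_half_up(mean(ec), 2),
       mean_intron_ratio = if (length(il))
         round_half_up(mean(il), 2) else NA_real_,
       n_pairs = length(pl))
}

#' Full microsynteny analysis of a region pair
#'
#' Pairs orthologues, finds blocks and reports per-block quality and
#' structural ratios.
#'
#' @param genes_a,genes_b `gene_models` data.frames.
#' @param homology homology table.
#' @param evalue_cut,identity_floor,max_gap tuning knobs (defaults
#'   1e-46, 0, 3).
#' @return data.frame with one row per block: ranges, gene counts,
#'   conserved counts, `quality` and ratio columns.
#' @export
analyze_synteny <- function(genes_a, genes_b, homology,
                            evalue_cut = 1e-46, identity_floor = 0,
                            max_gap = 3L) {
  pairs <- pair_homologs(genes_a, genes_b, homology, evalue_cut,
                         identity_floor)
  blocks <- find_blocks(genes_a, genes_b, pairs, max_gap)
  if (!length(blocks)) {
    return(data.frame(block = integer(), n_pairs = integer(),
                      quality = numeric()))
  }
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    q <- synteny_quality(b, genes_a, genes_b, homology, evalue_cut,
                         identity_floor)
    r <- ratio_stats(b$pairs, genes_a, genes_b)
    data.frame(block = i,
               a_start = b$a_range[1], a_end = b$a_range[2],
               b_start = b$b_range[1], b_end = b$b_range[2],
               n_pairs = nrow(b$pairs),
               total_a = q$total_a, total_b = q$total_b,
               conserved_a = q$conserved_a, conserved_b = q$conserved_b,
               quality = q$quality,
               protein_length_ratio = r$protein_length_ratio,
               exon_count_ratio = r$exon_count_ratio,
               mean_intron_ratio = r$mean_intron_ratio)
  }))
}
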