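## Synthetic data: toy genomes with gene/TE annotations, BAC pools with
## BamHI cloning junctions, fragmented scaffolds, homopolymer-biased
## error injection and diverged syntenic region pairs. Every generator is
## deterministic for a fixed seed and returns ground truth alongside the
## sequences so that the analysis stages can be tested against it.

BAMHI <- "GGATCC"

#' Default vector-junction sequences
#'
#' The 30 bp of cloning-vector sequence flanking each side of the BamHI
#' site, whose presence at a scaffold extreme marks a BAC border. These
#' are fixed synthetic stand-ins for a real vector's flanks; any 30 bp
#' pair free of `GGATCC` works.
#'
#' @return list with `left` and `right`, each a 30 bp DNA string.
#' @export
default_junctions <- function() {
  list(left  = "ACTGGCCGTCGTTTTACAACGTCGTGACTG",
       right = "TGTGTGGAATTGTGAGCGGATAACAATTTC")
}

## overwrite part of a sequence in place
splice_in <- function(seq, at, replacement) {
  paste0(substr(seq, 1, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

## pick n non-overlapping intervals of the given widths inside [lo, hi];
## returns starts (sorted) or NULL if it fails
place_intervals <- function(widths, lo, hi, occupied = NULL, tries = 200L) {
  starts <- integer(0)
  occ <- occupied
  for (w in widths) {
    ok <- FALSE
    for (t in seq_len(tries)) {
      s <- sample.int(hi - lo - w + 1L, 1L) + lo - 1L
      e <- s + w - 1L
      if (is.null(occ) || nrow(occ) == 0 ||
          all(e < occ[, 1] - 1L | s > occ[, 2] + 1L)) {
        occ <- rbind(occ, c(s, e))
        starts <- c(starts, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  starts
}

## simulate one gene's exon structure at a start position; exon count is
## geometric around a target mean, exon/intron lengths log-normal
sim_gene_structure <- function(start, mean_exons = 4.9, mean_exon_bp = 238,
                               mean_intron_bp = 393) {
  n_ex <- 1L + rgeom(1, 1 / mean_exons)
  exl <- pmax(30L, round(rlnorm(n_ex, log(mean_exon_bp) - 0.18, 0.6)))
  inl <- if (n_ex > 1)
    pmax(60L, round(rlnorm(n_ex - 1L, log(mean_intron_bp) - 0.18, 0.6)))
  else integer(0)
  st <- start + cumsum(c(0L, head(exl, -1) + inl))
  data.frame(start = st, end = st + exl - 1L)
}

#' Generate a toy annotated genome
#'
#' Random sequence at the requested GC content with simulated gene models
#' and transposable elements, plus planted long homopolymer runs and
#' dinucleotide tandem arrays so that downstream error injection and the
#' discrepancy census have realistic substrate (random sequence alone is
#' nearly free of runs longer than 10 nt).
#'
#' @param length genome length in bp (>= 10 kb).
#' @param gene_density genes per 100 kb (default 9.9).
#' @param te_fraction fraction of the genome covered by TEs (default 0.08).
#' @param gc GC fraction in (0, 1) (default 0.33).
#' @param seed integer seed; identical seeds give identical genomes.
#' @param hp_per_100kb planted homopolymer runs (length >= 11) per 100 kb
#'   (default 26).
#' @param dinuc_per_100kb planted dinucleotide arrays (>= 10 units) per
#'   100 kb (default 2).
#' @return an object of class `toy_genome`: list with `sequence`, `genes`
#'   (a `gene_models` data.frame, TEs included with `te_flag` set),
#'   `planted` (data.frame of planted repeat features) and `params`.
#' @export
make_genome <- function(length, gene_density = 9.9, te_fraction = 0.08,
                        gc = 0.33, seed = 1L, hp_per_100kb = 26,
                        dinuc_per_100kb = 2) {
  stopifnot(length >= 1e4, gc > 0, gc < 1, gene_density >= 0,
            te_fraction >= 0, te_fraction < 1)
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    plant_list <- list()
    occ <- matrix(numeric(0), ncol = 2)

    ## planted homopolymer runs, A/T-biased as in pyrosequencing substrates
    n_hp <- round(length / 1e5 * hp_per_100kb)
    if (n_hp > 0) {
      hp_len <- pmin(28L, 11L + rgeom(n_hp, 0.35))
      hp_base <- sample(DNA_BASES, n_hp, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4))
      st <- place_intervals(hp_len + 2L, 200L, length - 200L, occ)
      if (!is.null(st)) {
        for (i in seq_along(st)) {
          ## flank with a different base so the run is maximal as planted
          flank <- setdiff(DNA_BASES, hp_base[i])[1]
          chars[st[i]:(st[i] + hp_len[i] + 1L)] <-
            c(flank, rep(hp_base[i], hp_len[i]), flank)
          occ <- rbind(occ, c(st[i], st[i] + hp_len[i] + 1L))
          plant_list[[length(plant_list) + 1L]] <- data.frame(
            type = "homopolymer", start = st[i] + 1L,
            end = st[i] + hp_len[i], motif = hp_base[i])
        }
      }
    }
    ## planted dinucleotide arrays
    n_di <- round(length / 1e5 * dinuc_per_100kb)
    if (n_di > 0) {
      units <- sample(10:21, n_di, replace = TRUE)
      motifs <- sample(c("CT", "GA", "AT", "TG", "CA", "TC"), n_di,
                       replace = TRUE)
      st <- place_intervals(units * 2L + 2L, 200L, length - 200L, occ)
      if (!is.null(st)) {
        for (i in seq_along(st)) {
          flank <- setdiff(DNA_BASES, s2c(motifs[i]))[1]
          chars[st[i]:(st[i] + units[i] * 2L + 1L)] <-
            c(flank, rep(s2c(motifs[i]), units[i]), flank)
          occ <- rbind(occ, c(st[i], st[i] + units[i] * 2L + 1L))
          plant_list[[length(plant_list) + 1L]] <- data.frame(
            type = "dinucleotide", start = st[i] + 1L,
            end = st[i] + units[i] * 2L, motif = motifs[i])
        }
      }
    }
    seq <- c2s(chars)
    planted <- if (length(plant_list)) do.call(rbind, plant_list) else
      data.frame(type = character(), start = integer(), end = integer(),
                 motif = character(), stringsAsFactors = FALSE)

    ## gene models
    n_genes <- round(length / 1e5 * gene_density)
    feat_occ <- matrix(numeric(0), ncol = 2)
    gene_rows <- list()
    if (n_genes > 0) {
      for (i in seq_len(n_genes)) {
        placed <- FALSE
        for (t in 1:80) {
          cand <- sim_gene_structure(1L)
          span <- max(cand$end)
          if (span + 400L >= length) next
          s0 <- sample.int(length - span - 400L, 1L) + 200L
          cand$start <- cand$start + s0 - 1L
          cand$end <- cand$end + s0 - 1L
          gs <- min(cand$start); ge <- max(cand$end)
          if (nrow(feat_occ) == 0 ||
              all(ge < feat_occ[, 1] - 100L | gs > feat_occ[, 2] + 100L)) {
            feat_occ <- rbind(feat_occ, c(gs, ge))
            gene_rows[[length(gene_rows) + 1L]] <- list(
              id = sprintf("g%03d", i), exons = cand,
              strand = sample(c("+", "-"), 1L),
              protein = max(1L, round(exon_bp(cand) / 3)),
              est = runif(1) < 0.732)
            placed <- TRUE
            break
          }
        }
        if (!placed && length(gene_rows) == 0 && i == n_genes) {
          stop("genome too small to place a single gene at this density",
               call. = FALSE)
        }
      }
      if (length(gene_rows) == 0) {
        stop("genome too small to place a single gene at this density",
             call. = FALSE)
      }
    }

    ## transposable elements, kept clear of gene loci
    te_rows <- list()
    if (te_fraction > 0) {
      mean_te <- 4000
      n_te <- max(1L, round(te_fraction * length / mean_te))
      te_len <- pmax(500L, round(rlnorm(n_te, log(mean_te) - 0.125, 0.5)))
      fams <- sample(names(TE_CLASS), n_te, replace = TRUE,
                     prob = c(.10, .03, .05, .01, .01, .12, .15, .03, .50))
      for (i in seq_len(n_te)) {
        for (t in 1:80) {
          s <- sample.int(length - te_len[i] - 400L, 1L) + 200L
          e <- s + te_len[i] - 1L
          if (nrow(feat_occ) == 0 ||
              all(e < feat_occ[, 1] - 100L | s > feat_occ[, 2] + 100L)) {
            feat_occ <- rbind(feat_occ, c(s, e))
            te_rows[[length(te_rows) + 1L]] <- list(
              id = sprintf("te%03d", i), start = s, end = e,
              family = fams[i])
            break
          }
        }
      }
    }

    all_ids <- c(vapply(gene_rows, `[[`, character(1), "id"),
                 vapply(te_rows, `[[`, character(1), "id"))
    genes <- gene_models(
      gene_id = all_ids,
      scaffold_id = rep("genome", length(all_ids)),
      strand = c(vapply(gene_rows, `[[`, character(1), "strand"),
                 rep("+", length(te_rows))),
      exons = c(lapply(gene_rows, `[[`, "exons"),
                lapply(te_rows, function(t)
                  data.frame(start = t$start, end = t$end))),
      te_flag = c(rep(FALSE, length(gene_rows)), rep(TRUE, length(te_rows))),
      te_family = c(rep(NA_character_, length(gene_rows)),
                    vapply(te_rows, `[[`, character(1), "family")),
      est_support = c(vapply(gene_rows, `[[`, logical(1), "est"),
                      rep(FALSE, length(te_rows))),
      protein_length = c(vapply(gene_rows, function(g)
        as.integer(g$protein), integer(1)),
        rep(NA_integer_, length(te_rows))))

    structure(list(sequence = seq, genes = genes, planted = planted,
                   seed = seed,
                   params = list(length = length,
                                 gene_density = gene_density,
                                 te_fraction = te_fraction, gc = gc)),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy genome:", format(nchar(x$sequence), big.mark = ","), "bp;",
      sum(!x$genes$te_flag), "genes;", sum(x$genes$te_flag), "TEs;",
      nrow(x$planted), "planted repeat features\n")
  invisible(x)
}

#' Simulate a BAC pool from a toy genome
#'
#' Draws clone insert sizes around the library mean, snaps (or plants)
#' BamHI `GGATCC` sites at the insert boundaries, and extracts end
#' sequences (the rightmost one reverse-complemented, as Sanger BAC-end
#' reads are) and one marker per clone from a window covered by no other
#' clone, so that marker-based assignment has unique truth.
#'
#' @param genome a `toy_genome`.
#' @param n_clones number of clones.
#' @param insert_mean,insert_sd insert-size distribution in bp (defaults
#'   139000 and 10000, a typical BAC library).
#' @param junctions list with `left`/`right` 30 bp vector junctions.
#' @param seed integer seed.
#' @param end_len BAC-end read length (default 500 bp).
#' @param marker_len marker length (default 300 bp).
#' @return object of class `bac_pool`: list with `clones` (list of
#'   per-clone lists), `inserts` (named character), `markers`
#'   (data.frame), `truth` (data.frame clone_id/start/end),
#'   `genome_sequence` (the pool's working copy, with planted BamHI
#'   sites), `junctions` and `planted_sites`.
#' @export
make_bac_pool <- function(genome, n_clones, insert_mean = 139000,
                          insert_sd = 10000,
                          junctions = default_junctions(), seed = 1L,
                          end_len = 500L, marker_len = 300L) {
  stopifnot(inherits(genome, "toy_genome"))
  glen <- nchar(genome$sequence)
  if (insert_mean + 3 * insert_sd >= glen) {
    stop("insert_mean too large for this genome; lower insert_mean or ",
         "enlarge the genome", call. = FALSE)
  }
  stopifnot(nchar(junctions$left) == 30L, nchar(junctions$right) == 30L)
  with_seed(seed, {
    seq <- genome$sequence
    lens <- pmax(2L * end_len + 2L * marker_len,
                 round(rnorm(n_clones, insert_mean, insert_sd)))
    starts <- vapply(lens, function(L)
      sample.int(glen - L - 10L, 1L) + 5L, numeric(1))
    ends <- starts + lens - 1L
    planted_sites <- integer(0)
    ## snap to an existing GGATCC within 200 bp, else plant one
    snap <- function(pos) {
      win_lo <- max(1L, pos - 200L); win_hi <- min(glen - 5L, pos + 200L)
      hit <- regexpr(BAMHI, substr(seq, win_lo, win_hi), fixed = TRUE)
      if (hit > 0) return(win_lo + as.integer(hit) - 1L)
      seq <<- splice_in(seq, pos, BAMHI)
      planted_sites <<- c(planted_sites, pos)
      pos
    }
    for (i in seq_len(n_clones)) {
      starts[i] <- snap(starts[i])
      ends[i] <- snap(ends[i] - 5L) + 5L
    }
    ## extract after all planting so truth intervals match the final copy
    inserts <- substring(seq, starts, ends)
    ids <- sprintf("clone%02d", seq_len(n_clones))
    names(inserts) <- ids

    ## unique marker windows: covered by exactly one clone where possible
    cover <- integer(glen)
    for (i in seq_len(n_clones)) {
      cover[starts[i]:ends[i]] <- cover[starts[i]:ends[i]] + 1L
    }
    markers <- data.frame(id = character(), sequence = character(),
                          clone_id = character(), start = integer(),
                          stringsAsFactors = FALSE)
    clones <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      ## candidate marker starts inside the insert, away from the ends
      lo <- starts[i] + end_len; hi <- ends[i] - end_len - marker_len
      sole <- which(cover[lo:hi] == 1L) + lo - 1L
      mstart <- if (length(sole) >= marker_len) {
        ## first window fully single-covered
        runs <- rle(diff(sole) == 1L)
        cand <- sole[1]
        pos <- 1L
        for (j in seq_along(runs$lengths)) {
          if (runs$values[j] && runs$lengths[j] >= marker_len) {
            cand <- sole[pos]; break
          }
          pos <- pos + runs$lengths[j]
        }
        cand
      } else {
        warning("no single-coverage window for ", ids[i],
                "; marker may be ambiguous")
        starts[i] + (lens[i] %/% 2L)
      }
      mseq <- substr(seq, mstart, mstart + marker_len - 1L)
      mid <- sprintf("M_%s", ids[i])
      markers <- rbind(markers, data.frame(
        id = mid, sequence = mseq, clone_id = ids[i], start = mstart,
        stringsAsFactors = FALSE))
      clones[[i]] <- list(
        id = ids[i], expected_insert = insert_mean,
        marker_ids = mid,
        end_seqs = list(
          left = substr(inserts[[i]], 1L, end_len),
          right = revcomp(substr(inserts[[i]],
                                 nchar(inserts[[i]]) - end_len + 1L,
                                 nchar(inserts[[i]])))))
    }
    structure(list(clones = clones, inserts = inserts, markers = markers,
                   truth = data.frame(clone_id = ids, start = starts,
                                      end = ends),
                   genome_sequence = seq, junctions = junctions,
                   planted_sites = planted_sites, seed = seed),
              class = "bac_pool")
  })
}

#' @export
print.bac_pool <- function(x, ...) {
  cat("BAC pool:", length(x$clones), "clones, mean insert",
      format(round(mean(nchar(x$inserts))), big.mark = ","), "bp,",
      length(x$planted_sites), "planted BamHI site(s)\n")
  invisible(x)
}

#' Fragment an insert into a gapped scaffold
#'
#' Replaces `n_gaps` disjoint internal segments of the insert with runs
#' of `N` of the same length, emulating the unresolved gaps left by
#' contig scaffolding. Total length is conserved; gaps never touch the
#' sequence ends (borders must survive for assignment).
#'
#' @param insert DNA string.
#' @param n_gaps number of N stretches (>= 0).
#' @param gap_len_range integer pair, min/max gap length in bp.
#' @param seed integer seed.
#' @param end_margin minimum distance of any gap from either end
#'   (default 600 bp, enough to preserve junctions and end reads).
#' @param protect optional data.frame of `start`/`end` intervals that
#'   gaps must not overlap (e.g. a marker locus).
#' @return list with `sequence` and `gaps` (data.frame start/length).
#' @export
fragment_and_scaffold <- function(insert, n_gaps, gap_len_range = c(100, 2000),
                                  seed = 1L, end_margin = 600L,
                                  protect = NULL) {
  stopifnot(n_gaps >= 0)
  L <- nchar(insert)
  if (n_gaps == 0) {
    return(list(sequence = insert,
                gaps = data.frame(start = integer(), length = integer())))
  }
  with_seed(seed, {
    sizes <- seq(gap_len_range[1], gap_len_range[2])
    lens <- sizes[sample.int(length(sizes), n_gaps, replace = TRUE)]
    if (sum(lens) + 2L * end_margin + n_gaps >= L) {
      stop("gaps would touch the sequence ends; reduce n_gaps or gap ",
           "lengths", call. = FALSE)
    }
    occ <- if (!is.null(protect) && nrow(protect))
      cbind(protect$start, protect$end) else NULL
    starts <- place_intervals(lens, end_margin + 1L, L - end_margin, occ)
    if (is.null(starts)) {
      stop("could not place ", n_gaps, " disjoint gaps inside the insert",
           call. = FALSE)
    }
    seq <- insert
    ord <- order(starts)
    for (i in ord) {
      seq <- splice_in(seq, starts[i], strrep("N", lens[i]))
    }
    list(sequence = seq,
         gaps = data.frame(start = starts[ord], length = lens[ord]))
  })
}

#' Error-injection profile
#'
#' Parameters of the consensus-level error model: homopolymer runs at or
#' above the length threshold may be contracted by one to a few bases
#' (the dominant pyrosequencing error mode), long dinucleotide tandem
#' arrays may lose units, and N stretches may be added. Runs shorter than
#' the threshold are never touched.
#'
#' @param homopolymer_contraction_prob probability that an eligible run
#'   is contracted (default 0.6, matching the observed 15-of-26 rate).
#' @param contraction_size_range bases removed per contraction, min/max
#'   (default 1-3).
#' @param run_length_threshold minimum run length eligible for
#'   contraction (default 11).
#' @param dinucleotide_perturb_prob probability that an eligible array
#'   (>= 6 units) is perturbed (default 0.6).
#' @param dinucleotide_unit_loss units removed per perturbation, min/max
#'   (default 1-3).
#' @param n_gap_rate expected N stretches per 100 kb added by the profile
#'   itself (default 0; scaffolding gaps come from
#'   [fragment_and_scaffold()]).
#' @param seed integer seed.
#' @return list of class `error_profile`.
#' @export
error_profile <- function(homopolymer_contraction_prob = 0.6,
                          contraction_size_range = c(1L, 3L),
                          run_length_threshold = 11L,
                          dinucleotide_perturb_prob = 0.6,
                          dinucleotide_unit_loss = c(1L, 3L),
                          n_gap_rate = 0,
                          seed = 1L) {
  stopifnot(homopolymer_contraction_prob >= 0,
            homopolymer_contraction_prob <= 1,
            dinucleotide_perturb_prob >= 0, dinucleotide_perturb_prob <= 1,
            contraction_size_range[1] >= 1L, run_length_threshold >= 2L,
            n_gap_rate >= 0)
  structure(list(homopolymer_contraction_prob = homopolymer_contraction_prob,
                 contraction_size_range = contraction_size_range,
                 run_length_threshold = run_length_threshold,
                 dinucleotide_perturb_prob = dinucleotide_perturb_prob,
                 dinucleotide_unit_loss = dinucleotide_unit_loss,
                 n_gap_rate = n_gap_rate, seed = seed),
            class = "error_profile")
}

#' Inject consensus-level sequencing errors
#'
#' Applies an [error_profile()] to a sequence and records every planted
#' event with its reference position, motif, run length and signed length
#' change, so that the discrepancy census can be checked against ground
#' truth.
#'
#' @param seq DNA string (non-empty).
#' @param profile an `error_profile`.
#' @return list with `sequence` (mutated) and `events` (data.frame with
#'   columns `type`, `pos`, `motif`, `ref_len`, `delta_bp`).
#' @export
inject_errors <- function(seq, profile) {
  stopifnot(nchar(seq) > 0, inherits(profile, "error_profile"))
  with_seed(profile$seed, {
    events <- data.frame(type = character(), pos = integer(),
                         motif = character(), ref_len = integer(),
                         delta_bp = integer(), stringsAsFactors = FALSE)
    edits <- list()   # (pos, ref_width, replacement)
    occupied <- matrix(numeric(0), ncol = 2)

    runs <- ref_runs(seq, min_len = profile$run_length_threshold)
    for (i in seq_len(nrow(runs))) {
      if (runif(1) >= profile$homopolymer_contraction_prob) next
      d <- sample_range(profile$contraction_size_range[1],
                        profile$contraction_size_range[2])
      d <- min(d, runs$length[i] - 1L)
      edits[[length(edits) + 1L]] <- list(
        pos = runs$start[i], width = runs$length[i],
        repl = strrep(runs$base[i], runs$length[i] - d))
      occupied <- rbind(occupied, c(runs$start[i], runs$end[i]))
      events <- rbind(events, data.frame(
        type = "homopolymer", pos = runs$start[i], motif = runs$base[i],
        ref_len = runs$length[i], delta_bp = -d))
    }

    arrays <- ref_dinuc_arrays(seq, min_units = 6L)
    for (i in seq_len(nrow(arrays))) {
      if (runif(1) >= profile$dinucleotide_perturb_prob) next
      k <- sample_range(profile$dinucleotide_unit_loss[1],
                        profile$dinucleotide_unit_loss[2])
      k <- min(k, arrays$unit_count[i] - 2L)
      if (k < 1L) next
      edits[[length(edits) + 1L]] <- list(
        pos = arrays$start[i], width = arrays$total_bp[i],
        repl = strrep(arrays$unit[i], arrays$unit_count[i] - k))
      occupied <- rbind(occupied, c(arrays$start[i], arrays$end[i]))
      events <- rbind(events, data.frame(
        type = "dinucleotide", pos = arrays$start[i],
        motif = arrays$unit[i], ref_len = arrays$total_bp[i],
        delta_bp = -2L * k))
    }

    if (profile$n_gap_rate > 0) {
      n <- rpois(1, nchar(seq) / 1e5 * profile$n_gap_rate)
      if (n > 0) {
        lens <- sample(100:1000, n, replace = TRUE)
        starts <- place_intervals(lens, 600L, nchar(seq) - 600L, occupied)
        if (!is.null(starts)) {
          for (i in seq_along(starts)) {
            edits[[length(edits) + 1L]] <- list(
              pos = starts[i], width = lens[i], repl = strrep("N", lens[i]))
            events <- rbind(events, data.frame(
              type = "n_gap", pos = starts[i], motif = "N",
              ref_len = lens[i], delta_bp = 0L))
          }
        }
      }
    }

    ## apply right to left so earlier coordinates stay valid
    if (length(edits)) {
      ord <- order(vapply(edits, `[[`, numeric(1), "pos"),
                   decreasing = TRUE)
      for (ed in edits[ord]) {
        seq <- paste0(substr(seq, 1L, ed$pos - 1L), ed$repl,
                      substr(seq, ed$pos + ed$width, nchar(seq)))
      }
    }
    list(sequence = seq, events = events[order(events$pos), , drop = FALSE])
  })
}

#' Build a diverged syntenic region pair
#'
#' Region B is the toy genome as given; region A is an expanded copy:
#' every intron is scaled by `intron_scale`, `te_insertions` transposable
#' elements are inserted into intergenic space, and point substitutions
#' are applied at rate `divergence`. Gene order and orientation are
#' conserved, and the returned homology table pairs every orthologue
#' with its realised coding identity.
#'
#' @param genome a `toy_genome` (its non-TE genes become the orthologue
#'   set).
#' @param te_insertions number of TEs inserted into region A (default 15).
#' @param intron_scale multiplicative intron-length factor for region A
#'   (default 1.3).
#' @param divergence substitutions per site in `[0, 0.3]` (default 0.13).
#' @param seed integer seed.
#' @return list of class `synteny_pair` with `region_a`, `region_b`
#'   (each: `sequence` + `genes`), and `homology` (data.frame `gene_a`,
#'   `gene_b`, `identity`, `evalue`).
#' @export
make_synteny_pair <- function(genome, te_insertions = 15L,
                              intron_scale = 1.3, divergence = 0.13,
                              seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"),
            divergence >= 0, divergence <= 0.3, intron_scale >= 1)
  with_seed(seed, {
    bgenes <- genome$genes[!genome$genes$te_flag, , drop = FALSE]
    btes <- genome$genes[genome$genes$te_flag, , drop = FALSE]
    if (nrow(bgenes) == 0) stop("genome has no genes", call. = FALSE)
    bseq <- genome$sequence
    glen <- nchar(bseq)

    ## build region A with insertion edits (intron expansion + TEs)
    edits <- list()   # (at, insert) applied to B coordinates
    for (i in seq_len(nrow(bgenes))) {
      ex <- bgenes$exons[[i]]
      if (nrow(ex) < 2) next
      for (j in seq_len(nrow(ex) - 1L)) {
        ilen <- ex$start[j + 1L] - ex$end[j] - 1L
        extra <- round(ilen * (intron_scale - 1))
        if (extra > 0) {
          mid <- ex$end[j] + max(1L, ilen %/% 2L)
          edits[[length(edits) + 1L]] <- list(
            at = mid, ins = random_dna(extra, genome$params$gc),
            te = NA_character_)
        }
      }
    }
    if (te_insertions > 0) {
      ## intergenic insertion points (clear of every annotated feature)
      feat <- rbind(
        data.frame(s = bgenes$start, e = bgenes$end),
        if (nrow(btes)) data.frame(s = btes$start, e = btes$end))
      te_len <- pmax(500L, round(rnorm(te_insertions, 5000, 1000)))
      fams <- sample(names(TE_CLASS), te_insertions, replace = TRUE,
                     prob = c(.07, .02, .04, .01, .01, .15, .25, .05, .40))
      for (i in seq_len(te_insertions)) {
        for (t in 1:100) {
          at <- sample.int(glen - 400L, 1L) + 200L
          if (all(at < feat$s - 50L | at > feat$e + 50L)) {
            edits[[length(edits) + 1L]] <- list(
              at = at, ins = random_dna(te_len[i], 0.4), te = fams[i])
            break
          }
        }
      }
    }

    ## apply edits right to left, tracking cumulative offsets
    aseq <- bseq
    if (length(edits)) {
      ord <- order(vapply(edits, `[[`, numeric(1), "at"), decreasing = TRUE)
      for (ed in edits[ord]) {
        aseq <- paste0(substr(aseq, 1L, ed$at), ed$ins,
                       substr(aseq, ed$at + 1L, nchar(aseq)))
      }
    }
    ## coordinate lift B -> A: offset accumulated before each position
    eat <- vapply(edits, `[[`, numeric(1), "at")
    elen <- vapply(edits, function(e) nchar(e$ins), numeric(1))
    lift <- function(pos) {
      if (!length(eat)) return(pos)
      pos + vapply(pos, function(p) sum(elen[eat < p]), numeric(1))
    }

    ## region A gene models (lifted), plus inserted TEs
    a_exons <- lapply(seq_len(nrow(bgenes)), function(i) {
      ex <- bgenes$exons[[i]]
      data.frame(start = lift(ex$start), end = lift(ex$end))
    })
    te_edit <- Filter(function(e) !is.na(e$te), edits)
    a_ids <- paste0("a_", bgenes$gene_id)
    b_ids <- paste0("b_", bgenes$gene_id)
    a_genes <- gene_models(
      gene_id = c(a_ids,
                  paste0("a_", btes$gene_id),
                  if (length(te_edit))
                    sprintf("a_te_ins%02d", seq_along(te_edit))),
      scaffold_id = "region_a",
      strand = c(bgenes$strand, btes$strand,
                 rep("+", length(te_edit))),
      exons = c(a_exons,
                lapply(seq_len(nrow(btes)), function(i) {
                  ex <- btes$exons[[i]]
                  data.frame(start = lift(ex$start), end = lift(ex$end))
                }),
                lapply(te_edit, function(e) {
                  s <- lift(e$at) + 1L
                  data.frame(start = s, end = s + nchar(e$ins) - 1L)
                })),
      te_flag = c(rep(FALSE, nrow(bgenes)), rep(TRUE, nrow(btes)),
                  rep(TRUE, length(te_edit))),
      te_family = c(rep(NA_character_, nrow(bgenes)), btes$te_family,
                    vapply(te_edit, `[[`, character(1), "te")),
      est_support = c(bgenes$est_support, rep(FALSE, nrow(btes)),
                      rep(FALSE, length(te_edit))),
      protein_length = c(bgenes$protein_length,
                         rep(NA_integer_, nrow(btes) + length(te_edit))))

    b_genes <- genome$genes
    b_genes$gene_id <- paste0("b_", b_genes$gene_id)
    b_genes$scaffold_id <- "region_b"

    ## point substitutions on region A
    n_sub <- round(divergence * nchar(aseq))
    subs <- integer(0)
    if (n_sub > 0) {
      subs <- sample.int(nchar(aseq), n_sub)
      ach <- s2c(aseq)
      repl <- vapply(ach[subs], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      ach[subs] <- repl
      aseq <- c2s(ach)
    }

    ## realised identity per orthologue pair over the gene span
    a_span <- data.frame(s = vapply(a_exons, function(e) min(e$start),
                                    numeric(1)),
                         e = vapply(a_exons, function(e) max(e$end),
                                    numeric(1)))
    ident <- vapply(seq_len(nrow(a_span)), function(i) {
      hits <- sum(subs >= a_span$s[i] & subs <= a_span$e[i])
      100 * (1 - hits / (a_span$e[i] - a_span$s[i] + 1))
    }, numeric(1))
    homology <- data.frame(
      gene_a = a_ids, gene_b = b_ids,
      identity = round(ident, 1),
      evalue = 10^-(runif(length(a_ids), 60, 180)),
      stringsAsFactors = FALSE)

    structure(list(
      region_a = list(sequence = aseq, genes = a_genes),
      region_b = list(sequence = bseq, genes = b_genes),
      homology = homology, seed = seed,
      params = list(te_insertions = te_insertions,
                    intron_scale = intron_scale,
                    divergence = divergence)),
      class = "synteny_pair")
  })
}

#' @export
print.synteny_pair <- function(x, ...) {
  cat("synteny pair: region A", format(nchar(x$region_a$sequence),
                                       big.mark = ","), "bp vs region B",
      format(nchar(x$region_b$sequence), big.mark = ","), "bp;",
      nrow(x$homology), "orthologue pairs\n")
  invisible(x)
}

#' Simulated per-clone scaffold
#'
#' Convenience wrapper reproducing what assembly leaves behind for one
#' clone: the vector junction flanks attached to the insert (left
#' junction verbatim, right junction reverse-complemented), optional
#' fragmentation into N gaps and optional error injection.
#'
#' @param pool a `bac_pool`.
#' @param clone_id clone identifier within the pool.
#' @param n_gaps scaffolding gaps to introduce (default 7).
#' @param gap_len_range gap length range (default 100-2000 bp).
#' @param profile optional `error_profile` applied before fragmentation.
#' @param seed integer seed.
#' @return list with `id`, `sequence`, `reference` (pre-error,
#'   pre-fragmentation sequence), `gaps` and `events`.
#' @export
simulate_clone_scaffold <- function(pool, clone_id, n_gaps = 7L,
                                    gap_len_range = c(100, 2000),
                                    profile = NULL, seed = 1L) {
  stopifnot(inherits(pool, "bac_pool"))
  insert <- pool$inserts[[clone_id]]
  if (is.null(insert)) stop("unknown clone ", clone_id, call. = FALSE)
  reference <- paste0(pool$junctions$left, insert,
                      revcomp(pool$junctions$right))
  seq <- reference
  events <- NULL
  if (!is.null(profile)) {
    inj <- inject_errors(seq, profile)
    seq <- inj$sequence
    events <- inj$events
  }
  ## keep scaffolding gaps off the clone's marker locus (a marker fully
  ## swallowed by a gap could never anchor the clone, as in real data a
  ## marker in an unassembled region would simply not have been chosen)
  mk <- pool$markers[pool$markers$clone_id == clone_id, , drop = FALSE]
  tr <- pool$truth[pool$truth$clone_id == clone_id, , drop = FALSE]
  protect <- NULL
  if (nrow(mk) && nrow(tr)) {
    off <- mk$start - tr$start + 1L + nchar(pool$junctions$left)
    protect <- data.frame(start = off,
                          end = off + nchar(mk$sequence) - 1L)
  }
  frag <- fragment_and_scaffold(seq, n_gaps, gap_len_range, seed = seed,
                                protect = protect)
  list(id = paste0("scf_", clone_id), sequence = frag$sequence,
       reference = reference, gaps = frag$gaps, events = events)
}
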