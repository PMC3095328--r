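## Assignment of assembled contigs/scaffolds to BAC clones and clone
## completeness classification. Evidence comes from three sources:
## genetic markers anchored to clones, the 30 bp cloning-vector junction
## flanks found at scaffold extremes (three search modes), and BAC-end
## sequences. Scaffolds belonging to the same clone can be joined into
## an insert-size-constrained superscaffold.

#' Find marker hits on a scaffold set
#'
#' Each marker is placed by exact match or seed-and-extend alignment on
#' both strands; the best hit per marker (by identity x aligned length)
#' is kept, hits below the identity or length floor are suppressed, and
#' near-equal hits on other scaffolds are reported as ambiguities in the
#' `ambiguous` attribute.
#'
#' @param markers data.frame with `id` and `sequence` columns.
#' @param scaffolds data.frame with `id` and `sequence` columns.
#' @param min_identity identity floor in percent (default 95).
#' @param min_len aligned-length floor in bp (default 50).
#' @return data.frame of best hits: `marker_id`, `scaffold_id`, `start`,
#'   `end`, `strand`, `identity`, `aligned_len`.
#' @export
find_marker_hits <- function(markers, scaffolds, min_identity = 95,
                             min_len = 50L) {
  stopifnot(nrow(markers) >= 1)
  out <- list()
  cand_out <- list()
  ambi <- list()
  for (i in seq_len(nrow(markers))) {
    hits <- seed_search(markers$sequence[i], scaffolds,
                        min_identity = min_identity, min_len = min_len)
    if (nrow(hits) == 0) next
    key <- hits$identity * hits$aligned_len
    best <- which.max(key)
    near <- which(key >= 0.97 * key[best])
    others <- setdiff(unique(hits$scaffold_id[near]),
                      hits$scaffold_id[best])
    if (length(others)) {
      ambi[[markers$id[i]]] <- others
      message("marker ", markers$id[i], " has near-equal hits on: ",
              paste(others, collapse = ", "))
    }
    out[[length(out) + 1L]] <- cbind(
      data.frame(marker_id = markers$id[i], stringsAsFactors = FALSE),
      hits[best, c("scaffold_id", "start", "end", "strand", "identity",
                   "aligned_len")])
    cand_out[[length(cand_out) + 1L]] <- cbind(
      data.frame(marker_id = markers$id[i], stringsAsFactors = FALSE),
      hits[near, c("scaffold_id", "start", "end", "strand", "identity",
                   "aligned_len")])
  }
  empty <- data.frame(marker_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      aligned_len = numeric())
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "ambiguous") <- ambi
  attr(res, "candidates") <- if (length(cand_out))
    do.call(rbind, cand_out) else empty
  res
}

## mode-1 junction search within a window of each scaffold extreme
junction_hits_one <- function(scaffold_id, seq, junction, side_label,
                              window = 500L, max_mismatch = 2L) {
  out <- list()
  L <- nchar(seq)
  win_left <- substr(seq, 1L, min(L, window))
  win_right <- substr(seq, max(1L, L - window + 1L), L)
  right_off <- max(1L, L - window + 1L) - 1L
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") junction else revcomp(junction)
    for (endside in c("left", "right")) {
      win <- if (endside == "left") win_left else win_right
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(win),
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      for (j in seq_along(m)) {
        st <- Biostrings::start(m)[j]
        abs_start <- if (endside == "left") st else st + right_off
        offset <- if (endside == "left") abs_start - 1L else
          L - (abs_start + nchar(pat) - 1L)
        mm <- sum(s2c(pat) != s2c(substr(win, st, st + nchar(pat) - 1L)))
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = scaffold_id, clone_id = NA_character_,
          side = endside, method = "junction_at_extreme",
          junction = side_label, position = offset, strand = strand,
          identity = 100 * (nchar(pat) - mm) / nchar(pat),
          stringsAsFactors = FALSE)
      }
    }
  }
  out
}

#' Find BAC borders on scaffolds
#'
#' Three search modes: (1) the 30 bp vector-junction sequences searched
#' on both strands within a window of each scaffold extreme; (2) reads
#' containing a junction, whose insert-side flank is then placed near a
#' scaffold extreme (only when `reads` are supplied); (3) BAC-end
#' sequences of each clone aligned against the scaffolds.
#'
#' @param scaffolds data.frame with `id` and `sequence`.
#' @param clones list of clone records (each with `id` and `end_seqs`,
#'   a list with optional `left`/`right` sequences); may be `NULL`.
#' @param junction_left,junction_right 30 bp junction sequences.
#' @param reads optional character vector of individual reads.
#' @param window extreme-search window in bp for modes 1-2 (default 500).
#' @param min_identity,min_len floors for end-sequence alignment.
#' @return data.frame of border hits: `scaffold_id`, `clone_id`, `side`,
#'   `method`, `junction`, `position` (offset from the nearer scaffold
#'   end), `strand`, `identity`.
#' @export
find_borders <- function(scaffolds, clones = NULL, junction_left,
                         junction_right, reads = NULL, window = 500L,
                         min_identity = 95, min_len = 50L) {
  stopifnot(nchar(junction_left) == 30L, nchar(junction_right) == 30L)
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    out <- c(out,
             junction_hits_one(scaffolds$id[i], scaffolds$sequence[i],
                               junction_left, "left", window),
             junction_hits_one(scaffolds$id[i], scaffolds$sequence[i],
                               junction_right, "right", window))
  }
  ## mode 2: reads carrying a junction
  if (!is.null(reads) && length(reads)) {
    for (r in reads) {
      for (side in c("left", "right")) {
        j <- if (side == "left") junction_left else junction_right
        hitpos <- regexpr(j, r, fixed = TRUE)
        if (hitpos < 0) next
        flank <- if (side == "left")
          substr(r, hitpos + 30L, nchar(r)) else
          substr(r, 1L, hitpos - 1L)
        if (nchar(flank) < 30L) next
        hits <- seed_search(flank, scaffolds, min_identity, 30L)
        for (h in seq_len(nrow(hits))) {
          L <- nchar(scaffolds$sequence[scaffolds$id == hits$scaffold_id[h]])
          off <- min(hits$start[h] - 1L, L - hits$end[h])
          if (off > window) next
          out[[length(out) + 1L]] <- data.frame(
            scaffold_id = hits$scaffold_id[h], clone_id = NA_character_,
            side = if (hits$start[h] - 1L <= L - hits$end[h]) "left"
                   else "right",
            method = "read_with_junction", junction = side,
            position = off, strand = hits$strand[h],
            identity = hits$identity[h], stringsAsFactors = FALSE)
        }
      }
    }
  }
  ## mode 3: BAC-end sequences
  if (!is.null(clones)) {
    for (cl in clones) {
      for (side in names(cl$end_seqs)) {
        es <- cl$end_seqs[[side]]
        if (is.null(es) || !nzchar(es)) next
        hits <- seed_search(es, scaffolds, min_identity, min_len)
        if (nrow(hits) == 0) next
        key <- hits$identity * hits$aligned_len
        ## a BAC end marks a border: among near-equal hits prefer the
        ## one nearest a scaffold extreme
        cand <- which(key >= 0.999 * max(key))
        offs <- vapply(cand, function(h) {
          L <- nchar(scaffolds$sequence[scaffolds$id == hits$scaffold_id[h]])
          min(hits$start[h] - 1L, L - hits$end[h])
        }, numeric(1))
        h <- cand[which.min(offs)]
        L <- nchar(scaffolds$sequence[scaffolds$id == hits$scaffold_id[h]])
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = hits$scaffold_id[h], clone_id = cl$id,
          side = side, method = "bac_end_blast", junction = NA_character_,
          position = min(hits$start[h] - 1L, L - hits$end[h]),
          strand = hits$strand[h], identity = hits$identity[h],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(), clone_id = character(),
                      side = character(), method = character(),
                      junction = character(), position = integer(),
                      strand = character(), identity = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify clone completeness
#'
#' A total function of the assignment evidence: `complete` when both BAC
#' ends were found; `likely_complete` when one end was found on a
#' scaffold longer than 100 kb; `partial` when one end was found on a
#' scaffold of 60-100 kb; `fragmentary` when no end was found but a
#' marker hit exists; `unassigned` otherwise.
#'
#' @param ends_found number of BAC ends found (0, 1 or 2).
#' @param scaffold_length length of the assigned scaffold in bp.
#' @param has_marker logical; whether any marker hit supports the clone.
#' @return character label.
#' @export
classify_completeness <- function(ends_found, scaffold_length, has_marker) {
  n <- max(length(ends_found), length(scaffold_length), length(has_marker))
  ends_found <- rep_len(ends_found, n)
  scaffold_length <- rep_len(scaffold_length, n)
  has_marker <- rep_len(has_marker, n)
  ifelse(ends_found == 2, "complete",
  ifelse(ends_found == 1 & scaffold_length > 1e5, "likely_complete",
  ifelse(ends_found == 1 & scaffold_length >= 6e4 & scaffold_length <= 1e5,
         "partial",
  ifelse(ends_found == 0 & has_marker, "fragmentary", "unassigned"))))
}

#' Assign scaffolds to BAC clones
#'
#' Combines marker hits and BAC-end border hits into one assignment per
#' clone with a completeness label.
#'
#' @param scaffolds data.frame with `id` and `sequence`.
#' @param clones list of clone records (`id`, `marker_ids`, `end_seqs`).
#' @param markers data.frame with `id` and `sequence`.
#' @param junctions list with `left` and `right` 30 bp junctions.
#' @param reads optional reads for border mode 2.
#' @param min_identity,min_len alignment floors (defaults 95 percent,
#'   50 bp).
#' @param window extreme-search window (default 500 bp).
#' @return data.frame of class `bac_assignments`: one row per clone with
#'   `clone_id`, `scaffold_ids` (comma separated), `length` (largest
#'   assigned scaffold), `n_gap_stretches`, `ends_found`,
#'   `completeness`. Border and marker evidence are attached as
#'   attributes `borders` and `marker_hits`.
#' @export
assign_clones <- function(scaffolds, clones, markers, junctions,
                          reads = NULL, min_identity = 95, min_len = 50L,
                          window = 500L) {
  mh <- find_marker_hits(markers, scaffolds, min_identity, min_len)
  borders <- find_borders(scaffolds, clones, junctions$left,
                          junctions$right, reads = reads, window = window,
                          min_identity = min_identity, min_len = min_len)
  cands <- attr(mh, "candidates")
  rows <- lapply(clones, function(cl) {
    own_markers <- mh[mh$marker_id %in% cl$marker_ids, , drop = FALSE]
    own_ends <- borders[!is.na(borders$clone_id) &
                        borders$clone_id == cl$id, , drop = FALSE]
    ## corroboration: when a marker has near-equal hits on several
    ## scaffolds, the clone's end-sequence evidence arbitrates
    for (k in seq_len(nrow(own_markers))) {
      alts <- cands[cands$marker_id == own_markers$marker_id[k], ,
                    drop = FALSE]
      supported <- alts[alts$scaffold_id %in% own_ends$scaffold_id, ,
                        drop = FALSE]
      if (nrow(supported) &&
          !(own_markers$scaffold_id[k] %in% supported$scaffold_id)) {
        own_markers[k, colnames(supported)] <- supported[1, ]
      }
    }
    scf <- unique(c(own_markers$scaffold_id, own_ends$scaffold_id))
    ends_found <- length(unique(own_ends$side))
    len <- if (length(scf))
      max(nchar(scaffolds$sequence[scaffolds$id %in% scf])) else 0L
    gaps <- if (length(scf))
      sum(vapply(scaffolds$sequence[scaffolds$id %in% scf],
                 function(s) gap_stats(s)$n_stretches, numeric(1))) else 0L
    data.frame(
      clone_id = cl$id,
      scaffold_ids = paste(scf, collapse = ","),
      n_scaffolds = length(scf),
      length = len,
      n_gap_stretches = gaps,
      ends_found = ends_found,
      completeness = classify_completeness(ends_found, len,
                                           nrow(own_markers) > 0),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "borders") <- borders
  attr(res, "marker_hits") <- mh
  class(res) <- c("bac_assignments", "data.frame")
  res
}

#' Join scaffolds into an insert-size-constrained superscaffold
#'
#' Inserts one N gap per junction so that the final length matches the
#' expected BAC insert size. The total inserted gap is
#' `max(target_length - sum(part lengths), n_junctions * min_gap)`; when
#' the floor applies (parts already as long as the target) a warning is
#' raised and each junction receives the minimum gap.
#'
#' @param parts data.frame with columns `scaffold_id`, `length` and
#'   optionally `orientation` (`+`/`-`), in their final order; at least
#'   two rows.
#' @param target_length target final length (the library's average
#'   insert size).
#' @param min_gap minimum inserted gap per junction (default 100 N).
#' @param sequences optional named character vector of part sequences;
#'   when given, the joined sequence is returned too.
#' @return list of class `superscaffold`: `parts`, `inserted_gap_bp`
#'   (one per junction), `final_length`, `target_length`, and `sequence`
#'   when sequences were supplied.
#' @export
superscaffold <- function(parts, target_length, min_gap = 100L,
                          sequences = NULL) {
  stopifnot(nrow(parts) >= 2, target_length > 0)
  if (is.null(parts$orientation)) parts$orientation <- "+"
  n_junc <- nrow(parts) - 1L
  total_parts <- sum(parts$length)
  total_gap <- max(target_length - total_parts, n_junc * min_gap)
  if (target_length - total_parts < n_junc * min_gap) {
    warning("parts reach the target length; inserting minimum gaps of ",
            min_gap, " N per junction")
  }
  base <- total_gap %/% n_junc
  gaps <- rep(base, n_junc)
  gaps[n_junc] <- gaps[n_junc] + (total_gap - base * n_junc)
  out <- list(parts = parts, inserted_gap_bp = gaps,
              final_length = total_parts + total_gap,
              target_length = target_length)
  if (!is.null(sequences)) {
    seqs <- vapply(seq_len(nrow(parts)), function(i) {
      s <- sequences[[parts$scaffold_id[i]]]
      if (parts$orientation[i] == "-") revcomp(s) else s
    }, character(1))
    joined <- seqs[1]
    for (i in seq_len(n_junc)) {
      joined <- paste0(joined, strrep("N", gaps[i]), seqs[i + 1L])
    }
    out$sequence <- joined
  }
  class(out) <- "superscaffold"
  out
}

#' @export
print.superscaffold <- function(x, ...) {
  cat("superscaffold of", nrow(x$parts), "parts; gaps",
      paste(x$inserted_gap_bp, collapse = ", "), "N; final",
      format(x$final_length, big.mark = ","), "bp (target",
      format(x$target_length, big.mark = ","), "bp)\n")
  invisible(x)
}

#' Write assignments as TSV
#' @param assignments a `bac_assignments` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write.table(as.data.frame(assignments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
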