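## Alignment machinery.
##
## Two primitives live here: (1) an anchored global aligner for comparing
## two versions of the same locus (reference vs assembly), which chains
## exact shared unique k-mers and runs affine dynamic programming only on
## the short regions between anchors, masking N stretches out of the
## comparison; (2) a seed-and-extend local search used for marker and
## BAC-end placement. Scoring throughout: match +1, mismatch -2, gap
## opening -4, gap extension -1 (a length-L gap costs 4 + L); N never
## matches anything, including another N.

nw_substitution_matrix <- function() {
  m <- matrix(-2, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m)[1:4] <- 1
  m
}

## all k-mers of a string as a character vector (vectorised substring)
kmer_vector <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

## exact shared k-mers, unique in both sequences, strictly co-linear
find_anchors <- function(ref, test, k = 31L) {
  kr <- kmer_vector(ref, k)
  kt <- kmer_vector(test, k)
  ur <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  ut <- !(duplicated(kt) | duplicated(kt, fromLast = TRUE))
  ## drop k-mers touching N
  ur <- ur & !grepl("N", kr, fixed = TRUE)
  ut <- ut & !grepl("N", kt, fixed = TRUE)
  rpos <- which(ur)
  tpos <- which(ut)
  hit <- match(kr[rpos], kt[tpos])
  keep <- !is.na(hit)
  a <- data.frame(ref_pos = rpos[keep], test_pos = tpos[hit[keep]])
  a <- a[order(a$ref_pos), , drop = FALSE]
  ## greedy strictly-increasing filter on the test side
  if (nrow(a) > 1) {
    keep <- logical(nrow(a))
    last <- 0L
    for (i in seq_len(nrow(a))) {
      if (a$test_pos[i] > last) { keep[i] <- TRUE; last <- a$test_pos[i] }
    }
    a <- a[keep, , drop = FALSE]
  }
  rownames(a) <- NULL
  a
}

## global alignment of one short chunk; returns gapped strings
chunk_align <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(list(a = "", b = ""))
  if (nchar(a) == 0) return(list(a = strrep("-", nchar(b)), b = b))
  if (nchar(b) == 0) return(list(a = a, b = strrep("-", nchar(a))))
  if (a == b) return(list(a = a, b = b))
  p <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = nw_substitution_matrix(),
    gapOpening = 4, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(p)),
       b = as.character(Biostrings::alignedSubject(p)))
}

#' Anchored global alignment of two versions of the same locus
#'
#' Chains exact shared 31-mers (unique in both sequences) and aligns only
#' the intervening regions with affine dynamic programming. Columns where
#' either sequence carries `N` are flagged as excluded from comparison
#' (`n_gap_excluded`); the assembly's N stretches therefore never count
#' as discrepancies.
#'
#' @param ref reference sequence (e.g. a finished Sanger sequence).
#' @param test test sequence of the same locus; may contain `N`.
#' @param k anchor k-mer size (default 31).
#' @return an object of class `locus_alignment`: a list with gapped
#'   strings `ref_aln`/`test_aln`, the input sequences, `excluded`
#'   (data.frame of excluded reference intervals) and `n_anchors`.
#' @export
align_locus <- function(ref, test, k = 31L) {
  stopifnot(nchar(ref) > 0, nchar(test) > 0)
  ref <- toupper(ref); test <- toupper(test)
  check_dna(ref, "ref"); check_dna(test, "test")
  anchors <- find_anchors(ref, test, k)
  if (nrow(anchors) == 0) {
    ## crude identity estimate from shared k-mer content at small k
    ksm <- 11L
    shared <- length(intersect(kmer_vector(ref, ksm), kmer_vector(test, ksm)))
    est <- round(100 * shared / max(1, nchar(ref) - ksm + 1), 1)
    stop("no shared ", k, "-mer anchors between the two sequences; ",
         "they do not look like the same locus (shared 11-mer content ~",
         est, "%)", call. = FALSE)
  }
  ## collapse runs of diagonal-adjacent anchors into matched blocks
  d <- which(!(c(FALSE, diff(anchors$ref_pos) == 1L) &
               c(FALSE, diff(anchors$test_pos) == 1L)))
  block_start <- anchors[d, , drop = FALSE]
  block_end_idx <- c(d[-1] - 1L, nrow(anchors))
  block_end <- anchors[block_end_idx, , drop = FALSE]

  pieces_r <- character(0); pieces_t <- character(0)
  cur_r <- 1L; cur_t <- 1L
  for (i in seq_len(nrow(block_start))) {
    rs <- block_start$ref_pos[i]; ts <- block_start$test_pos[i]
    re <- block_end$ref_pos[i] + k - 1L; te <- block_end$test_pos[i] + k - 1L
    ## trim overlap with what has already been emitted
    if (rs < cur_r || ts < cur_t) {
      shift <- max(cur_r - rs, cur_t - ts)
      rs <- rs + shift; ts <- ts + shift
      if (rs > re || ts > te) next
    }
    ## align the gap before this block
    ga <- substr(ref, cur_r, rs - 1L)
    gb <- substr(test, cur_t, ts - 1L)
    ch <- chunk_align(ga, gb)
    pieces_r <- c(pieces_r, ch$a, substr(ref, rs, re))
    pieces_t <- c(pieces_t, ch$b, substr(test, ts, te))
    cur_r <- re + 1L; cur_t <- te + 1L
  }
  ch <- chunk_align(substr(ref, cur_r, nchar(ref)),
                    substr(test, cur_t, nchar(test)))
  pieces_r <- c(pieces_r, ch$a)
  pieces_t <- c(pieces_t, ch$b)
  ref_aln <- paste(pieces_r, collapse = "")
  test_aln <- paste(pieces_t, collapse = "")
  stopifnot(nchar(ref_aln) == nchar(test_aln))

  rc <- s2c(ref_aln); tc <- s2c(test_aln)
  excl_col <- rc == "N" | tc == "N"
  ref_pos <- cumsum(rc != "-")
  excl <- data.frame(ref_start = integer(), ref_end = integer())
  if (any(excl_col)) {
    r <- rle(excl_col)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    w <- which(r$values)
    excl <- data.frame(ref_start = pmax(1L, ref_pos[s[w]]),
                       ref_end = pmax(1L, ref_pos[e[w]]))
  }
  structure(list(ref_aln = ref_aln, test_aln = test_aln,
                 ref = ref, test = test,
                 excluded = excl, n_anchors = nrow(anchors), k = k),
            class = "locus_alignment")
}

#' Score of a gapped alignment under the package scoring scheme
#'
#' Match +1, mismatch -2, a length-L gap costs 4 + L. N columns score as
#' mismatches. Used mainly to compare the anchored aligner against an
#' unanchored dynamic-programming oracle.
#'
#' @param aln a `locus_alignment`, or a list with `ref_aln`/`test_aln`.
#' @return numeric alignment score.
#' @export
alignment_score <- function(aln) {
  a <- s2c(aln$ref_aln); b <- s2c(aln$test_aln)
  sub <- nw_substitution_matrix()
  both <- a != "-" & b != "-"
  s <- sum(sub[cbind(a[both], b[both])])
  for (g in list(rle(a == "-"), rle(b == "-"))) {
    gl <- g$lengths[g$values]
    s <- s - sum(4 + gl)
  }
  s
}

#' @export
print.locus_alignment <- function(x, ...) {
  diffs <- sum(s2c(x$ref_aln) != s2c(x$test_aln) &
               !(s2c(x$ref_aln) == "N" | s2c(x$test_aln) == "N"))
  cat("locus alignment:", nchar(x$ref), "bp ref vs", nchar(x$test),
      "bp test;", x$n_anchors, "anchors;", nrow(x$excluded),
      "excluded interval(s);", diffs, "difference column(s)\n")
  invisible(x)
}

## ---- seed-and-extend local search ----------------------------------------

## Best local placement of `query` in `subject` (both plain strings).
## Exact match fast path, then 31-mer seeds extended by global-local
## alignment of the query against a window around the seed hit.
seed_hit_one <- function(query, subject, k = 31L, n_seeds = 8L,
                         margin = 60L) {
  qlen <- nchar(query)
  subj <- Biostrings::DNAString(subject)
  ## fast path: exact occurrence
  mexact <- Biostrings::matchPattern(query, subj)
  if (length(mexact) > 0) {
    st <- Biostrings::start(mexact)[1]
    return(list(start = st, end = st + qlen - 1L, identity = 100,
                aligned_len = qlen, score = qlen))
  }
  if (qlen < k) return(NULL)
  offs <- unique(pmax(1L, round(seq(1L, qlen - k + 1L,
                                    length.out = min(n_seeds, qlen - k + 1L)))))
  best <- NULL
  tried <- numeric(0)
  for (o in offs) {
    seed <- substr(query, o, o + k - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- Biostrings::matchPattern(seed, subj)
    for (p in head(Biostrings::start(m), 5L)) {
      ws <- max(1L, p - o + 1L - margin)
      we <- min(nchar(subject), p - o + qlen + margin)
      if (any(abs(tried - ws) < margin)) next
      tried <- c(tried, ws)
      win <- substr(subject, ws, we)
      pa <- Biostrings::pairwiseAlignment(
        query, win, type = "global-local",
        substitutionMatrix = nw_substitution_matrix(),
        gapOpening = 4, gapExtension = 1)
      alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
      ident <- 100 * Biostrings::nmatch(pa) / alen
      sc <- Biostrings::score(pa)
      if (is.null(best) || sc > best$score) {
        best <- list(start = ws + Biostrings::start(Biostrings::subject(pa)) - 1L,
                     end = ws + Biostrings::end(Biostrings::subject(pa)) - 1L,
                     identity = ident, aligned_len = alen, score = sc)
      }
    }
  }
  best
}

## Search a query against a scaffold set on both strands.
## Returns a data.frame of hits (possibly empty).
seed_search <- function(query, scaffolds, min_identity = 95,
                        min_len = 50L) {
  out <- list()
  rc <- revcomp(query)
  for (i in seq_len(nrow(scaffolds))) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc
      h <- seed_hit_one(q, scaffolds$sequence[i])
      if (is.null(h)) next
      if (h$identity < min_identity || h$aligned_len < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = scaffolds$id[i], start = h$start, end = h$end,
        strand = strand, identity = h$identity,
        aligned_len = h$aligned_len, score = h$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), aligned_len = numeric(),
                      score = numeric()))
  }
  do.call(rbind, out)
}
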