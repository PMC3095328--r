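## Independent oracles used across the suite. These deliberately take
## the dumbest correct route (full dynamic programming, regular-
## expression enumeration, exhaustive search) and share no code with the
## package implementations they check.

## full affine-gap global alignment score (Gotoh), same scoring scheme
## as the package: match +1, mismatch -2, a length-L gap costs 4 + L,
## N never matches
oracle_nw_score <- function(a, b, match = 1, mismatch = -2,
                            open = 4, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## brute-force N50: test every candidate length
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

## brute-force SSR enumerator: every (start, unit-length) combination is
## extended unit by unit; left-extendable arrays are discarded as
## non-maximal; then the same thresholds, primitivity and
## lower-unit-first overlap rules are applied
oracle_ssrs <- function(seq, thresholds = c(10, 12, 12, 16, 20, 24)) {
  primitive <- function(unit) {
    u <- nchar(unit)
    if (u == 1) return(TRUE)
    for (d in seq_len(u - 1)) {
      if (u %% d == 0 &&
          paste(rep(substr(unit, 1, d), u / d), collapse = "") == unit)
        return(FALSE)
    }
    TRUE
  }
  n <- nchar(seq)
  acc <- data.frame(start = integer(), end = integer(),
                    unit_len = integer(), total_bp = integer())
  for (u in 1:6) {
    taken <- data.frame(start = integer(), end = integer())
    s <- 1L
    while (s <= n - 2L * u + 1L) {
      unit <- substr(seq, s, s + u - 1L)
      if (grepl("N", unit, fixed = TRUE) || !primitive(unit)) {
        s <- s + 1L; next
      }
      cnt <- 1L
      while (substr(seq, s + cnt * u, s + (cnt + 1L) * u - 1L) == unit)
        cnt <- cnt + 1L
      ## must not be extendable by one unit to the left
      left_ok <- s - u < 1L || substr(seq, s - u, s - 1L) != unit
      bp <- cnt * u
      e <- s + bp - 1L
      if (cnt >= 2L && left_ok && bp >= thresholds[u] &&
          !(nrow(taken) && any(s <= taken$end & e >= taken$start))) {
        taken <- rbind(taken, data.frame(start = s, end = e))
        if (!(nrow(acc) && any(s <= acc$end & e >= acc$start))) {
          acc <- rbind(acc, data.frame(start = s, end = e, unit_len = u,
                                       total_bp = bp))
        }
      }
      s <- s + 1L
    }
  }
  acc[order(acc$start), , drop = FALSE]
}

## exhaustive block finder: every interval of A-sorted pairs is checked
## for validity, maximal valid intervals with >= 2 pairs are kept
oracle_blocks <- function(ia, ib, paired_a, paired_b, max_gap = 3L) {
  k <- length(ia)
  gapn <- function(paired, i, j) {
    lo <- min(i, j) + 1L; hi <- max(i, j) - 1L
    if (lo > hi) 0L else sum(!paired[lo:hi])
  }
  valid <- function(s, e) {
    if (e == s) return(TRUE)
    all(vapply((s + 1L):e, function(t) {
      gapn(paired_a, ia[t - 1L], ia[t]) <= max_gap &&
        gapn(paired_b, ib[t - 1L], ib[t]) <= max_gap
    }, logical(1)))
  }
  out <- list()
  for (s in seq_len(k)) {
    for (e in s:k) {
      if (!valid(s, e)) next
      maximal <- (s == 1L || !valid(s - 1L, e)) &&
        (e == k || !valid(s, e + 1L))
      if (maximal && e - s + 1L >= 2L) out[[length(out) + 1L]] <- c(s, e)
    }
  }
  out
}

## small random DNA helper for the tests
rand_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## tiny gene-model factory for synteny tests: single-exon genes at the
## given starts unless exon structures are supplied
mk_genes <- function(ids, starts, te = FALSE, protein = 100L,
                     exons = NULL, scaffold = "s") {
  if (is.null(exons)) {
    exons <- lapply(starts, function(s) data.frame(start = s, end = s + 999))
  }
  gene_models(ids, scaffold, "+", exons, te_flag = te,
              protein_length = ifelse(rep_len(te, length(ids)), NA_integer_,
                                      as.integer(protein)))
}
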