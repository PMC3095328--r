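#' @importFrom stats rnorm runif rpois rgeom rlnorm setNames sd
#' @importFrom utils head tail read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## split / join single sequences
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] accepting and
#' returning plain character strings (alphabet `A/C/G/T/N`).
#'
#' @param x a single DNA string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Truncate (not round) to `digits` decimals; a tiny epsilon absorbs
## floating-point representation error so that e.g. 0.79 stays 0.79.
trunc_dec <- function(x, digits = 0L) {
  m <- 10^digits
  trunc(x * m + sign(x) * 1e-9) / m
}

## Round half-up (R's round() is half-to-even).
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

## Run a block with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Random DNA string of length n with the requested GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c2s(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

## sample one integer uniformly from [lo, hi] (safe for lo == hi)
sample_range <- function(lo, hi) {
  v <- seq(lo, hi)
  v[sample.int(length(v), 1L)]
}

## Maximal runs of a regular expression class; returns start/end/length.
regex_runs <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             length = as.integer(len))
}

## GC percentage of the non-N portion of a sequence (full precision).
gc_percent <- function(seq) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  acgt <- sum(counts[DNA_BASES])
  if (acgt == 0) return(NA_real_)
  100 * sum(counts[c("C", "G")]) / acgt
}

## Validate a DNA string over A/C/G/T/N.
check_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq)) {
    stop(what, " contains characters outside the ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", " alphabet", call. = FALSE)
  }
  invisible(seq)
}
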