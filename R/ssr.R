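## Microsatellite (SSR) detection. Perfect tandem arrays with unit length
## 1-6 bp above a class-specific minimum array length; the detector scans
## each unit length by comparing the sequence against itself shifted by
## the unit, which yields maximal perfect arrays directly.

#' Default SSR minimum array lengths
#'
#' Minimum total array lengths (bp) per motif unit length 1..6:
#' 10 bp for mononucleotides, 12 bp for di- and trinucleotides, 16 bp
#' for tetranucleotides, 20 bp for pentanucleotides and 24 bp for
#' hexanucleotides.
#'
#' @return named integer vector of length 6.
#' @export
ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 12L, `3` = 12L, `4` = 16L, `5` = 20L, `6` = 24L)
}

## TRUE if `unit` is not a repetition of a shorter unit.
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(unit, 1L, d), u / d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical SSR motif
#'
#' The lexicographically smallest string among all rotations of the unit
#' and of its reverse complement, so that e.g. `TC`, `CT`, `GA` and `AG`
#' all report as `AG`.
#'
#' @param unit repeat unit (1-6 bp).
#' @return canonical motif string.
#' @export
canonical_motif <- function(unit) {
  u <- nchar(unit)
  rots <- function(s) vapply(seq_len(u) - 1L, function(i) {
    paste0(substr(s, i + 1L, u), substr(s, 1L, i))
  }, character(1))
  min(c(rots(unit), rots(revcomp(unit))))
}

## maximal perfect arrays at one unit length; internal workhorse
tandem_arrays <- function(seq, u, min_units = 2L, min_bp = 0L,
                          require_primitive = TRUE) {
  n <- nchar(seq)
  if (n < 2L * u) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_count = integer(), total_bp = integer()))
  }
  ch <- s2c(seq)
  ok <- ch != "N"
  eq <- ch[seq_len(n - u)] == ch[(u + 1L):n] &
    ok[seq_len(n - u)] & ok[(u + 1L):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (j in keep) {
    i <- starts[j]                       # array starts here
    span <- r$lengths[j] + u             # length of the perfect region
    unit <- substr(seq, i, i + u - 1L)
    if (require_primitive && !is_primitive_unit(unit)) next
    cnt <- span %/% u                    # whole units only
    bp <- cnt * u
    if (cnt < min_units || bp < min_bp) next
    out[[length(out) + 1L]] <- data.frame(
      start = i, end = i + bp - 1L, unit = unit,
      unit_count = cnt, total_bp = bp, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_count = integer(), total_bp = integer()))
  }
  do.call(rbind, out)
}

#' Find microsatellites (SSRs) in a sequence
#'
#' Reports maximal perfect tandem arrays with unit lengths 1-6 bp whose
#' total array length (whole units) reaches the class minimum. When a
#' region qualifies at more than one unit length the smallest unit wins
#' and overlapping reports at larger units are suppressed. `N` breaks
#' arrays.
#'
#' @param seq DNA string over `A/C/G/T/N`.
#' @param thresholds minimum array length (bp) per unit length 1..6; see
#'   [ssr_thresholds()].
#' @param scaffold_id optional identifier copied into the output.
#' @return data.frame with columns `scaffold_id`, `start`, `end`, `motif`
#'   (canonical), `unit`, `unit_len`, `unit_count`, `total_bp`.
#' @export
find_ssrs <- function(seq, thresholds = ssr_thresholds(),
                      scaffold_id = NA_character_) {
  check_dna(seq, "sequence")
  found <- list()
  occupied <- matrix(numeric(0), ncol = 2)  # accepted intervals
  for (u in 1:6) {
    cand <- tandem_arrays(seq, u, min_units = 2L,
                          min_bp = unname(thresholds[as.character(u)]))
    if (nrow(cand) == 0) next
    cand <- cand[order(cand$start), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (nrow(occupied) &&
          any(s <= occupied[, 2] & e >= occupied[, 1])) next
      occupied <- rbind(occupied, c(s, e))
      found[[length(found) + 1L]] <- data.frame(
        scaffold_id = scaffold_id, start = s, end = e,
        motif = canonical_motif(cand$unit[i]), unit = cand$unit[i],
        unit_len = u, unit_count = cand$unit_count[i],
        total_bp = cand$total_bp[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit = character(), unit_len = integer(),
                      unit_count = integer(), total_bp = integer()))
  }
  res <- do.call(rbind, found)
  res[order(res$start), , drop = FALSE]
}

#' Find SSRs across a set of scaffolds
#' @param records data.frame with `id` and `sequence` columns.
#' @inheritParams find_ssrs
#' @return combined SSR data.frame.
#' @export
find_ssrs_set <- function(records, thresholds = ssr_thresholds()) {
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    find_ssrs(records$sequence[i], thresholds, scaffold_id = records$id[i])
  }))
}

#' Write SSRs as BED (0-based half-open intervals)
#' @param ssrs SSR data.frame from [find_ssrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(ssrs, path) {
  bed <- data.frame(chrom = ssrs$scaffold_id, start = ssrs$start - 1L,
                    end = ssrs$end,
                    name = sprintf("(%s)%d", ssrs$motif, ssrs$unit_count))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
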