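## Assembly summary statistics: N50, N-gap (scaffolding gap) accounting,
## totals, means, GC content and read coverage. Report views truncate
## means to integers and percentages to one decimal, the convention used
## in the package's report tables; full-precision values are kept
## alongside for machine use.

#' N50 length
#'
#' The largest length L in `lengths` such that sequences of length >= L
#' together contain at least half of the total bases.
#'
#' @param lengths numeric vector of sequence lengths, all positive.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  ls <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(ls))      # numeric cumsum avoids integer overflow
  ls[which(cs >= cs[length(cs)] / 2)[1]]
}

#' N-gap statistics of one sequence
#'
#' Maximal runs of `N` are the scaffolding gaps. The reported fraction is
#' truncated to one decimal (report precision); `gap_fraction_full` keeps
#' full precision.
#'
#' @param seq a DNA string over `A/C/G/T/N`.
#' @return a list with `stretches` (data.frame of start/end/length),
#'   `n_stretches`, `total_gap_bp`, `gap_fraction` (percent, one decimal)
#'   and `gap_fraction_full`.
#' @export
gap_stats <- function(seq) {
  check_dna(seq, "sequence")
  st <- regex_runs(seq, "N+")
  gap_bp <- sum(st$length)
  full <- if (nchar(seq) > 0) 100 * gap_bp / nchar(seq) else 0
  list(stretches = st,
       n_stretches = nrow(st),
       total_gap_bp = gap_bp,
       gap_fraction = trunc_dec(full, 1),
       gap_fraction_full = full)
}

#' Report-view mean: total divided by count, truncated to integer
#'
#' The truncation (rather than rounding) convention is what the package's
#' report tables use for average sequence sizes.
#'
#' @param total_bp total bases.
#' @param n number of sequences.
#' @return truncated integer mean.
#' @export
report_mean <- function(total_bp, n) trunc_dec(total_bp / n, 0)

#' Summarise an assembly
#'
#' @param records data.frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param total_read_bp optional total read length used to compute fold
#'   coverage as `total_read_bp / total_bp`.
#' @return a list of class `assembly_stats`.
#' @export
summarize_assembly <- function(records, total_read_bp = NULL) {
  stopifnot(nrow(records) >= 1)
  lens <- nchar(records$sequence)
  gaps <- lapply(records$sequence, gap_stats)
  gap_bp <- sum(vapply(gaps, `[[`, numeric(1), "total_gap_bp"))
  n_stretch <- sum(vapply(gaps, `[[`, numeric(1), "n_stretches"))
  total <- sum(lens)
  non_n <- total - gap_bp
  gc <- vapply(records$sequence, gc_percent, numeric(1), USE.NAMES = FALSE)
  acgt <- lens - vapply(gaps, `[[`, numeric(1), "total_gap_bp")
  gc_all <- sum(gc * acgt, na.rm = TRUE) / sum(acgt[!is.na(gc)])
  out <- list(
    n_sequences = nrow(records),
    total_bp = total,
    mean_bp = report_mean(total, nrow(records)),
    mean_bp_full = total / nrow(records),
    n50_bp = n50(lens),
    largest_bp = max(lens),
    n_gap_stretches = n_stretch,
    gap_bp = gap_bp,
    gap_fraction = trunc_dec(100 * gap_bp / total, 1),
    non_n_bp = non_n,
    gc_percent = gc_all,
    coverage_x = if (is.null(total_read_bp)) NA_real_ else
      total_read_bp / total)
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly of", x$n_sequences, "sequence(s)\n")
  cat("  total bp:      ", format(x$total_bp, big.mark = ","), "\n")
  cat("  mean size:     ", format(x$mean_bp, big.mark = ","), "\n")
  cat("  N50:           ", format(x$n50_bp, big.mark = ","), "\n")
  cat("  largest:       ", format(x$largest_bp, big.mark = ","), "\n")
  cat("  N stretches:   ", x$n_gap_stretches, "totalling",
      format(x$gap_bp, big.mark = ","), "bp (", x$gap_fraction, "%)\n")
  cat("  GC percent:    ", round(x$gc_percent, 1), "\n")
  if (!is.na(x$coverage_x))
    cat("  coverage:      ", round(x$coverage_x, 1), "x\n")
  invisible(x)
}

#' Write an assembly report as TSV
#' @param stats an `assembly_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_report <- function(stats, path) {
  rows <- data.frame(
    metric = c("No. of sequences", "No. of bases", "Average size",
               "N50 size", "Largest size", "N stretches", "N bases",
               "N fraction (%)", "GC (%)", "Coverage (x)"),
    value = c(stats$n_sequences, stats$total_bp, stats$mean_bp,
              stats$n50_bp, stats$largest_bp, stats$n_gap_stretches,
              stats$gap_bp, stats$gap_fraction,
              round_half_up(stats$gc_percent, 1),
              if (is.na(stats$coverage_x)) NA else
                trunc_dec(stats$coverage_x, 0)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
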