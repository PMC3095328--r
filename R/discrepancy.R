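## Discrepancy census between two sequence versions of the same locus
## (a finished reference vs a pyrosequencing-style assembly). Differences
## are classified into homopolymer-length errors, dinucleotide
## tandem-repeat errors, substitutions and other indels; N stretches are
## excluded from comparison. The census joins homopolymer discrepancies
## to the reference run-length distribution and reports a per-10-kb rate.

## maximal single-base runs of the reference, length >= min_len
ref_runs <- function(ref, min_len = 2L) {
  ch <- s2c(ref)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% DNA_BASES
  data.frame(base = r$values[keep], start = starts[keep], end = ends[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

## perfect dinucleotide tandem arrays (primitive unit, >= min_units units)
ref_dinuc_arrays <- function(ref, min_units = 6L) {
  tandem_arrays(ref, 2L, min_units = min_units)
}

#' Classify the differences of a locus alignment
#'
#' Walks the difference columns of an [align_locus()] alignment and
#' classifies them:
#' * `homopolymer` — an indel inside or adjacent to a maximal single-base
#'   reference run of length >= 2; one record per run, with the signed
#'   length change.
#' * `dinucleotide_repeat` — length changes inside or at the edge of a
#'   perfect dinucleotide tandem array (>= 6 units in the reference); one
#'   record per array.
#' * `substitution` — a mismatch column in unique context.
#' * `other_indel` — remaining indels.
#' * `n_gap_excluded` — one record per excluded (N-masked) reference
#'   interval; these carry the interval, not a length change.
#'
#' @param aln a `locus_alignment` from [align_locus()].
#' @param min_run minimum reference run length for homopolymer
#'   attribution (default 2).
#' @param min_dinuc_units minimum units of a reference dinucleotide array
#'   (default 6).
#' @return a data.frame with columns `kind`, `ref_pos`, `ref_motif`,
#'   `ref_len`, `test_motif`, `test_len`, `delta_bp`.
#' @export
classify_discrepancies <- function(aln, min_run = 2L, min_dinuc_units = 6L) {
  stopifnot(inherits(aln, "locus_alignment"))
  rc <- s2c(aln$ref_aln); tc <- s2c(aln$test_aln)
  ncol_ <- length(rc)
  excl <- rc == "N" | tc == "N"
  ref_pos <- cumsum(rc != "-")          # ref position at/before column
  test_pos <- cumsum(tc != "-")
  diffcol <- (rc != tc) & !excl

  runs <- ref_runs(aln$ref, min_len = min_run)
  arrays <- ref_dinuc_arrays(aln$ref, min_units = min_dinuc_units)

  rec <- list()
  add <- function(kind, ref_p, ref_motif, ref_len, test_motif, test_len,
                  delta, group = NA_character_) {
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, ref_pos = ref_p, ref_motif = ref_motif,
      ref_len = ref_len, test_motif = test_motif, test_len = test_len,
      delta_bp = delta, group = group, stringsAsFactors = FALSE)
  }

  if (any(diffcol)) {
    r <- rle(diffcol)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bidx <- which(r$values)
    for (j in bidx) {
      s <- starts[j]; e <- ends[j]
      cols <- s:e
      refchars <- rc[cols][rc[cols] != "-"]
      testchars <- tc[cols][tc[cols] != "-"]
      ## reference span touched by the block ([p, p] between-bases for a
      ## pure insertion)
      p1 <- if (length(refchars)) ref_pos[cols[rc[cols] != "-"][1]] else
        ref_pos[s]
      p2 <- if (length(refchars)) max(ref_pos[cols]) else ref_pos[s]
      delta <- length(testchars) - length(refchars)
      has_indel <- any(rc[cols] == "-") || any(tc[cols] == "-")

      ## 1) dinucleotide array context (overlap or adjacency)
      ai <- which(arrays$start - 1L <= p2 + 1L & arrays$end + 1L >= p1)
      if (length(ai) && has_indel) {
        a <- arrays[ai[1], ]
        add("dinucleotide_repeat", a$start,
            sprintf("(%s)_%d", a$unit, a$unit_count), a$total_bp,
            NA_character_, NA_integer_, delta,
            group = paste0("dinuc:", a$start))
        next
      }
      ## 2) homopolymer run context: all columns inside/adjacent one run
      ri <- which(runs$start - 1L <= p1 & runs$end + 1L >= p2)
      if (length(ri) && has_indel) {
        rr <- runs[ri[1], ]           # leftmost attribution
        add("homopolymer", rr$start, sprintf("(%s)_%d", rr$base, rr$length),
            rr$length, NA_character_, NA_integer_, delta,
            group = paste0("hp:", rr$start))
        next
      }
      ## 3) leftovers: mismatch columns are substitutions, indel columns
      ##    one other_indel per block
      mm <- cols[rc[cols] != "-" & tc[cols] != "-" & rc[cols] != tc[cols]]
      for (m in mm) {
        add("substitution", ref_pos[m], rc[m], 1L, tc[m], 1L, 0L)
      }
      if (has_indel) {
        ind <- cols[rc[cols] == "-" | tc[cols] == "-"]
        d2 <- sum(tc[ind] != "-") - sum(rc[ind] != "-")
        add("other_indel", p1, c2s(rc[ind][rc[ind] != "-"]),
            sum(rc[ind] != "-"), c2s(tc[ind][tc[ind] != "-"]),
            sum(tc[ind] != "-"), d2)
      }
    }
  }

  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(kind = character(), ref_pos = integer(),
               ref_motif = character(), ref_len = integer(),
               test_motif = character(), test_len = integer(),
               delta_bp = integer(), group = character(),
               stringsAsFactors = FALSE)

  ## merge blocks that hit the same run/array into one record
  if (nrow(records)) {
    grouped <- !is.na(records$group)
    if (any(grouped)) {
      gs <- split(records[grouped, , drop = FALSE], records$group[grouped])
      merged <- do.call(rbind, lapply(gs, function(g) {
        g1 <- g[1, , drop = FALSE]
        g1$delta_bp <- sum(g$delta_bp)
        g1
      }))
      records <- rbind(merged, records[!grouped, , drop = FALSE])
    }
    ## fill in the observed test-side motif for run/array records
    for (i in which(records$kind %in% c("homopolymer", "dinucleotide_repeat"))) {
      p1 <- records$ref_pos[i]
      p2 <- p1 + records$ref_len[i] - 1L
      cols <- which(ref_pos >= p1 & ref_pos <= p2 & rc != "-")
      cols <- seq(min(cols), max(cols))
      tseg <- c2s(tc[cols][tc[cols] != "-"])
      records$test_len[i] <- nchar(tseg)
      records$test_motif[i] <- compact_motif(tseg)
    }
    records <- records[order(records$ref_pos), , drop = FALSE]
    records$group <- NULL
    rownames(records) <- NULL
  }

  ## excluded intervals as n_gap_excluded records
  if (nrow(aln$excluded)) {
    ex <- data.frame(kind = "n_gap_excluded", ref_pos = aln$excluded$ref_start,
                     ref_motif = NA_character_,
                     ref_len = aln$excluded$ref_end - aln$excluded$ref_start + 1L,
                     test_motif = NA_character_, test_len = NA_integer_,
                     delta_bp = NA_integer_, stringsAsFactors = FALSE)
    records <- rbind(records, ex)
    rownames(records) <- NULL
  }
  records
}

## compress a sequence segment into run-length notation, e.g. A15CA13 ->
## "A_15 C A_13"; single runs of a dinucleotide array stay verbatim-ish.
compact_motif <- function(seg) {
  if (!nchar(seg)) return("-")
  r <- rle(s2c(seg))
  paste(ifelse(r$lengths > 1,
               sprintf("(%s)_%d", r$values, r$lengths), r$values),
        collapse = "")
}

#' Census of reference homopolymer runs joined to discrepancies
#'
#' Counts the maximal single-base runs of the reference per base class
#' (`A/T` vs `C/G`) and run length, and joins homopolymer discrepancy
#' records to their run length.
#'
#' @param ref reference sequence.
#' @param records discrepancy records from [classify_discrepancies()].
#' @param min_run minimum run length entering the census (default 5).
#' @return data.frame of class `run_census` with columns `class`,
#'   `length`, `count`, `discrepant`.
#' @export
run_census <- function(ref, records, min_run = 5L) {
  runs <- ref_runs(ref, min_len = min_run)
  runs$class <- ifelse(runs$base %in% c("A", "T"), "A/T", "C/G")
  hp <- records[records$kind == "homopolymer", , drop = FALSE]
  if (nrow(hp)) {
    known <- paste(hp$ref_pos) %in% paste(ref_runs(ref, 2L)$start)
    if (any(!known)) {
      stop("homopolymer record(s) reference a run absent from ref at ",
           paste(hp$ref_pos[!known], collapse = ", "), call. = FALSE)
    }
  }
  cen <- do.call(rbind, lapply(split(runs, runs$class), function(g) {
    tab <- table(g$length)
    data.frame(class = g$class[1], length = as.integer(names(tab)),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(cen)) {
    cen <- data.frame(class = character(), length = integer(),
                      count = integer())
  }
  cen$discrepant <- 0L
  if (nrow(hp)) {
    hp$class <- ifelse(substr(hp$ref_motif, 2, 2) %in% c("A", "T"),
                       "A/T", "C/G")
    for (i in seq_len(nrow(hp))) {
      j <- which(cen$class == hp$class[i] & cen$length == hp$ref_len[i])
      if (length(j)) cen$discrepant[j] <- cen$discrepant[j] + 1L
    }
  }
  rownames(cen) <- NULL
  class(cen) <- c("run_census", "data.frame")
  cen
}

#' Report view of a run census
#'
#' Bins A/T run lengths <= 10 together and C/G lengths 5-7 together,
#' the layout used for the package's homopolymer report table.
#'
#' @param census a `run_census` data.frame.
#' @return data.frame with columns `class`, `length_bin`, `count`,
#'   `discrepant`.
#' @export
report_run_census <- function(census) {
  bin_of <- function(class, len) {
    if (class == "A/T" && len <= 10) "<=10"
    else if (class == "C/G" && len >= 5 && len <= 7) "5-7"
    else as.character(len)
  }
  census$length_bin <- mapply(bin_of, census$class, census$length)
  agg <- aggregate(cbind(count, discrepant) ~ class + length_bin,
                   data = census, FUN = sum)
  suppressWarnings(num <- as.numeric(sub("[^0-9].*", "", agg$length_bin)))
  agg[order(agg$class, !grepl("^[<5]", agg$length_bin), num), , drop = FALSE]
}

#' Discrepancy rate per 10 kb
#'
#' Counts only homopolymer and dinucleotide tandem-repeat discrepancies
#' (the two classes that make up a pyrosequencing-vs-finished-sequence
#' census) and reports `10000 * n / ref_length` rounded half-up to one
#' decimal.
#'
#' @param records discrepancy records, or an integer count.
#' @param ref_length reference length in bp.
#' @return rate per 10 kb, one decimal.
#' @export
discrepancy_rate <- function(records, ref_length) {
  stopifnot(ref_length > 0)
  n <- if (is.data.frame(records)) {
    sum(records$kind %in% c("homopolymer", "dinucleotide_repeat"))
  } else {
    as.numeric(records)
  }
  round_half_up(1e4 * n / ref_length, 1)
}

#' Full accuracy report for a reference/assembly pair
#'
#' Runs [align_locus()], [classify_discrepancies()], [run_census()] and
#' [discrepancy_rate()] and assembles the result.
#'
#' @param ref reference sequence.
#' @param test test (assembly) sequence; may contain N stretches.
#' @param ... passed to [classify_discrepancies()].
#' @return list of class `accuracy_report`.
#' @export
accuracy_report <- function(ref, test, ...) {
  aln <- align_locus(ref, test)
  records <- classify_discrepancies(aln, ...)
  ex <- records[records$kind == "n_gap_excluded", , drop = FALSE]
  n_bp <- sum(ex$ref_len)
  out <- list(
    ref_length = nchar(ref),
    n_stretches = nrow(ex),
    n_stretch_bp = n_bp,
    n_stretch_pct = trunc_dec(100 * n_bp / nchar(ref), 1),
    homopolymer_discrepancies = sum(records$kind == "homopolymer"),
    dinucleotide_discrepancies = sum(records$kind == "dinucleotide_repeat"),
    substitutions = sum(records$kind == "substitution"),
    other_indels = sum(records$kind == "other_indel"),
    rate_per_10kb = discrepancy_rate(records, nchar(ref)),
    records = records,
    census = run_census(ref, records))
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy report over", format(x$ref_length, big.mark = ","),
      "bp of reference\n")
  cat("  N stretches:", x$n_stretches, "totalling", x$n_stretch_bp,
      "bp (", x$n_stretch_pct, "% )\n")
  cat("  homopolymer discrepancies:  ", x$homopolymer_discrepancies, "\n")
  cat("  dinucleotide discrepancies: ", x$dinucleotide_discrepancies, "\n")
  cat("  substitutions / other indels:", x$substitutions, "/",
      x$other_indels, "\n")
  cat("  rate:", x$rate_per_10kb, "per 10 kb\n")
  invisible(x)
}

#' Write an accuracy report as TSV
#'
#' Layout: an N-stretch line, the per-length homopolymer census block and
#' an "Other" block listing dinucleotide-repeat records.
#'
#' @param report an `accuracy_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("Length of reference\t", report$ref_length, "\n", sep = "", file = con)
  cat("Stretches of Ns\t", report$n_stretches, "\t", report$n_stretch_bp,
      " bp (", report$n_stretch_pct, "%)\n", sep = "", file = con)
  cat("class\tlength\tcount\tdiscrepant\n", file = con)
  rep_view <- report_run_census(report$census)
  for (i in seq_len(nrow(rep_view))) {
    cat(rep_view$class[i], rep_view$length_bin[i], rep_view$count[i],
        rep_view$discrepant[i], sep = "\t", file = con)
    cat("\n", file = con)
  }
  cat("Other\tref\ttest\n", file = con)
  din <- report$records[report$records$kind == "dinucleotide_repeat", ,
                        drop = FALSE]
  for (i in seq_len(nrow(din))) {
    cat("", din$ref_motif[i], din$test_motif[i], sep = "\t", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}
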