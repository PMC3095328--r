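## Annotation census: gene-model summary statistics, SSR totals and
## transposon-content accounting over a set of annotated scaffolds.
##
## Denominator conventions (fixed by the package's report arithmetic):
## gene density and TE percentages are computed on the total sequence
## length including N stretches; SSR percentage and kb-per-SSR on the
## non-N length. Gene-level percentages are rounded half-up, TE
## percentages truncated, at report precision.

#' Gene density per 100 kb (one decimal, half-up)
#' @param n_genes number of protein-coding genes (TEs excluded).
#' @param total_bp total analysed sequence length including Ns.
#' @return genes per 100 kb, one decimal.
#' @export
gene_density <- function(n_genes, total_bp) {
  round_half_up(1e5 * n_genes / total_bp, 1)
}

#' Percentage of genes with transcript (EST) support (one decimal)
#' @param n_supported,n_genes counts.
#' @export
est_support_pct <- function(n_supported, n_genes) {
  round_half_up(100 * n_supported / n_genes, 1)
}

#' SSR fraction of the sequence (two decimals)
#' @param ssr_bp total SSR bases.
#' @param non_n_bp sequence length excluding N stretches.
#' @export
ssr_fraction_pct <- function(ssr_bp, non_n_bp) {
  round_half_up(100 * ssr_bp / non_n_bp, 2)
}

#' Kilobases of sequence per SSR (one decimal)
#' @param non_n_bp sequence length excluding N stretches.
#' @param n_ssrs SSR count.
#' @export
kb_per_ssr <- function(non_n_bp, n_ssrs) {
  if (n_ssrs == 0) return(NA_real_)
  round_half_up(non_n_bp / n_ssrs / 1000, 1)
}

#' TE percentage of analysed sequence (truncated)
#' @param te_bp total element bases.
#' @param total_bp total analysed sequence including Ns.
#' @param digits decimals kept (2 for family rows, 1 for class totals).
#' @export
te_percent <- function(te_bp, total_bp, digits = 2L) {
  trunc_dec(100 * te_bp / total_bp, digits)
}

#' Summarise gene models over a scaffold set
#'
#' TE-flagged models are excluded from all gene statistics. The intron
#' fraction of coding regions is computed per gene and then averaged.
#'
#' @param genes a `gene_models` data.frame.
#' @param scaffolds data.frame with `id` and `sequence` columns.
#' @return a list of class `annotation_summary`.
#' @export
summarize_genes <- function(genes, scaffolds) {
  g <- genes[!genes$te_flag, , drop = FALSE]
  if (nrow(g) == 0) stop("no non-TE gene models", call. = FALSE)
  lens <- nchar(scaffolds$sequence)
  total <- sum(lens)
  gapinfo <- lapply(scaffolds$sequence, gap_stats)
  non_n <- total - sum(vapply(gapinfo, `[[`, numeric(1), "total_gap_bp"))

  exbp <- vapply(g$exons, exon_bp, numeric(1))
  exn <- vapply(g$exons, nrow, numeric(1))
  intrlens <- lapply(g$exons, intron_lengths)
  intrbp <- vapply(intrlens, sum, numeric(1))
  pct_intron <- 100 * intrbp / (intrbp + exbp)

  per_scaffold <- data.frame(
    scaffold_id = scaffolds$id,
    length = lens,
    n_genes = vapply(scaffolds$id, function(s) sum(g$scaffold_id == s),
                     numeric(1)),
    gc = vapply(scaffolds$sequence, gc_percent, numeric(1),
                USE.NAMES = FALSE))
  per_scaffold$density <- 1e5 * per_scaffold$n_genes / per_scaffold$length

  out <- list(
    total_bp = total,
    non_n_bp = non_n,
    n_genes = nrow(g),
    n_est_supported = sum(g$est_support),
    est_support_pct = est_support_pct(sum(g$est_support), nrow(g)),
    gene_density = gene_density(nrow(g), total),
    mean_exon_bp = sum(exbp) / sum(exn),
    mean_intron_bp = if (sum(lengths(intrlens)) > 0)
      sum(unlist(intrlens)) / sum(lengths(intrlens)) else NA_real_,
    exons_per_gene = sum(exn) / nrow(g),
    pct_intron_in_coding = mean(pct_intron),
    mean_protein_aa = mean(g$protein_length, na.rm = TRUE),
    gc_percent = sum(per_scaffold$gc * lens, na.rm = TRUE) / sum(lens),
    per_scaffold = per_scaffold,
    density_sd = sd(per_scaffold$density),
    gc_sd = sd(per_scaffold$gc))
  class(out) <- "annotation_summary"
  out
}

#' Summarise SSR content
#'
#' @param records SSR data.frame from [find_ssrs()] or [find_ssrs_set()].
#' @param total_bp total sequence length including Ns.
#' @param non_n_bp sequence length excluding N stretches.
#' @return list with `count`, `bp`, `percent` (of non-N sequence) and
#'   `kb_per_ssr` (`NA` when no SSRs).
#' @export
summarize_ssrs <- function(records, total_bp, non_n_bp) {
  stopifnot(total_bp > 0, non_n_bp > 0)
  n <- if (is.null(records)) 0L else nrow(records)
  bp <- if (n) sum(records$total_bp) else 0
  list(count = n, bp = bp,
       percent = if (n) ssr_fraction_pct(bp, non_n_bp) else 0,
       kb_per_ssr = kb_per_ssr(non_n_bp, n))
}

TE_CLASS <- c(CACTA = "DNA transposon", hAT = "DNA transposon",
              MULE = "DNA transposon", PIF = "DNA transposon",
              helitron = "DNA transposon",
              Copia = "Retrotransposon", Gypsy = "Retrotransposon",
              NonLTR = "Retrotransposon", Unclassified = "Retrotransposon")

#' Transposon-content accounting
#'
#' Per-family copy numbers, total lengths and percentages of the analysed
#' sequence, plus class totals for DNA transposons and retrotransposons.
#' Unknown family labels are binned as `Unclassified` with a warning.
#' Report percentages are truncated: two decimals for family rows, one
#' for class totals.
#'
#' @param te_models `gene_models` rows with `te_flag` set.
#' @param total_bp total analysed sequence length including Ns.
#' @return a list of class `te_summary` with elements `families`
#'   (data.frame), `classes` (data.frame) and `total_bp`.
#' @export
summarize_tes <- function(te_models, total_bp) {
  te <- te_models[te_models$te_flag, , drop = FALSE]
  fam <- te$te_family
  unknown <- !is.na(fam) & !(fam %in% names(TE_CLASS))
  if (any(unknown)) {
    warning("unknown TE family label(s) binned as Unclassified: ",
            paste(unique(fam[unknown]), collapse = ", "))
  }
  fam[is.na(fam) | unknown] <- "Unclassified"
  lens <- te$end - te$start + 1
  families <- do.call(rbind, lapply(names(TE_CLASS), function(f) {
    idx <- fam == f
    data.frame(family = f, class = TE_CLASS[[f]],
               copies = sum(idx), total_bp = sum(lens[idx]),
               stringsAsFactors = FALSE)
  }))
  families$percent <- te_percent(families$total_bp, total_bp, 2)
  families$percent_full <- 100 * families$total_bp / total_bp
  ## order family rows by class then name
  families <- families[order(families$class, families$family), , drop = FALSE]
  classes <- do.call(rbind, lapply(unique(TE_CLASS), function(cl) {
    idx <- families$class == cl
    data.frame(class = cl, copies = sum(families$copies[idx]),
               total_bp = sum(families$total_bp[idx]),
               stringsAsFactors = FALSE)
  }))
  classes$percent <- te_percent(classes$total_bp, total_bp, 1)
  classes$percent_full <- 100 * classes$total_bp / total_bp
  rownames(families) <- rownames(classes) <- NULL
  structure(list(families = families, classes = classes,
                 total_bp = total_bp), class = "te_summary")
}

#' @export
print.te_summary <- function(x, ...) {
  cat("Transposon content over", format(x$total_bp, big.mark = ","), "bp\n")
  print(x$families[, c("family", "class", "copies", "total_bp", "percent")],
        row.names = FALSE)
  print(x$classes[, c("class", "copies", "total_bp", "percent")],
        row.names = FALSE)
  invisible(x)
}
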