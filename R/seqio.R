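## Readers and writers for the standard formats the pipeline touches:
## FASTA (scaffolds, markers, BAC ends), GFF3 gene/TE annotations and the
## tabular homology input. Containers are plain data.frames so that every
## downstream stage can be driven from files or built in code.

#' Read a FASTA file into a scaffold table
#'
#' Sequences are uppercased; the record order of the file is preserved.
#' Identifiers are the first whitespace-delimited token of each header and
#' must be unique within the file.
#'
#' @param path path to a FASTA file (gzipped accepted).
#' @param on_invalid what to do with characters outside `A/C/G/T/N`:
#'   `"reject"` (default) raises an error, `"mask"` replaces them with `N`.
#' @return a data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, on_invalid = c("reject", "mask")) {
  on_invalid <- match.arg(on_invalid)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_invalid == "reject") {
      stop("record(s) with characters outside A/C/G/T/N: ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a scaffold table to FASTA
#'
#' @param records data.frame with columns `id` and `sequence`, or a named
#'   character vector.
#' @param path output path.
#' @param width line width of the sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

## ---- gene models ----------------------------------------------------------

TE_FAMILIES <- c("CACTA", "hAT", "MULE", "PIF", "helitron",
                 "Copia", "Gypsy", "NonLTR", "Unclassified")

#' Construct a gene-model table
#'
#' The unit of annotation used throughout the package: one row per gene or
#' transposable element, with its exon structure held in a list column.
#' Coordinates are 1-based closed (the R/Bioconductor convention); GFF3
#' input/output uses the same convention so no shifting occurs on IO.
#'
#' @param gene_id,scaffold_id,strand character vectors (strand `+` or `-`).
#' @param exons list of two-column data.frames (`start`, `end`), one per
#'   gene, sorted and non-overlapping.
#' @param te_flag logical; `TRUE` marks a transposable element.
#' @param te_family TE superfamily label (see `TE_FAMILIES`), `NA` for genes.
#' @param est_support logical; whether the model has transcript support.
#' @param protein_length protein length in amino acids (`NA` for TEs).
#' @return a data.frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, scaffold_id, strand, exons,
                        te_flag = FALSE, te_family = NA_character_,
                        est_support = FALSE, protein_length = NA_integer_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, scaffold_id = scaffold_id,
                   strand = strand,
                   start = vapply(exons, function(e)
                     if (nrow(e)) min(e$start) else NA_real_, numeric(1)),
                   end = vapply(exons, function(e)
                     if (nrow(e)) max(e$end) else NA_real_, numeric(1)),
                   te_flag = rep_len(te_flag, n),
                   te_family = rep_len(te_family, n),
                   est_support = rep_len(est_support, n),
                   protein_length = rep_len(protein_length, n),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  validate_gene_models(df)
}

validate_gene_models <- function(df) {
  stopifnot(all(df$strand %in% c("+", "-")))
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (nrow(ex) == 0) stop("gene ", df$gene_id[i], " has zero exons")
    if (is.unsorted(ex$start) ||
        (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))) {
      stop("exons of ", df$gene_id[i], " are unsorted or overlapping")
    }
    if (any(ex$start < df$start[i]) || any(ex$end > df$end[i])) {
      stop("exon outside parent span for ", df$gene_id[i])
    }
    if (!df$te_flag[i] && !is.na(df$protein_length[i]) &&
        df$protein_length[i] < 1) {
      stop("protein_length must be >= 1 for gene ", df$gene_id[i])
    }
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

## total exon / intron bp for one gene row
exon_bp <- function(ex) sum(ex$end - ex$start + 1)
intron_lengths <- function(ex) {
  if (nrow(ex) < 2) return(integer(0))
  ex$start[-1] - ex$end[-nrow(ex)] - 1L
}

#' Read gene and transposable-element models from GFF3
#'
#' Understands `gene`/`mRNA` features with `exon` children (linked via
#' `Parent`) and flat `transposable_element` features. Attributes
#' `te_family`, `est_support` and `protein_length` are picked up when
#' present.
#'
#' @param path path to a GFF3 file.
#' @return a `gene_models` data.frame.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_attr <- function(name, default) {
    if (name %in% colnames(md)) as.vector(md[[name]]) else
      rep(default, length(gr))
  }
  ids <- as.character(get_attr("ID", NA_character_))
  parents <- md$Parent
  parent1 <- if (is.null(parents)) rep(NA_character_, length(gr)) else
    vapply(as.list(parents), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))

  is_parent <- type %in% c("gene", "mRNA", "transposable_element")
  is_exon <- type == "exon"
  if (any(!is_parent & !is_exon)) {
    keep_other <- type[!is_parent & !is_exon]
    warning("ignoring feature type(s): ", paste(unique(keep_other), collapse = ", "))
  }
  pidx <- which(is_parent)
  ## mRNA nested under gene: keep the outermost record per ID chain
  rows <- lapply(pidx, function(i) {
    id <- ids[i]
    if (is.na(id)) stop("parent feature without ID at record ", i)
    kids <- which(is_exon & parent1 == id)
    ex <- if (length(kids)) {
      data.frame(start = GenomicRanges::start(gr)[kids],
                 end = GenomicRanges::end(gr)[kids])
    } else {
      data.frame(start = GenomicRanges::start(gr)[i],
                 end = GenomicRanges::end(gr)[i])
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) {
      if (type[i] == "transposable_element") strand <- "+"
      else stop("unknown strand for feature ", id)
    }
    if (any(ex$start < GenomicRanges::start(gr)[i]) ||
        any(ex$end > GenomicRanges::end(gr)[i])) {
      stop("exon outside parent span for ", id)
    }
    list(gene_id = id,
         scaffold_id = as.character(GenomicRanges::seqnames(gr)[i]),
         strand = strand,
         te_flag = type[i] == "transposable_element",
         te_family = as.character(get_attr("te_family", NA_character_)[i]),
         est_support = isTRUE(as.logical(get_attr("est_support", NA)[i])),
         protein_length = suppressWarnings(
           as.integer(get_attr("protein_length", NA_integer_)[i])),
         exons = ex)
  })
  ## drop mRNA records duplicating a gene record with the same exons
  keep <- !(type[pidx] == "mRNA" & parent1[pidx] %in% ids[type == "gene"])
  rows <- rows[keep]
  gene_models(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    scaffold_id = vapply(rows, `[[`, character(1), "scaffold_id"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    exons = lapply(rows, `[[`, "exons"),
    te_flag = vapply(rows, `[[`, logical(1), "te_flag"),
    te_family = vapply(rows, `[[`, character(1), "te_family"),
    est_support = vapply(rows, `[[`, logical(1), "est_support"),
    protein_length = vapply(rows, `[[`, integer(1), "protein_length"))
}

#' Write gene models to GFF3
#'
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- genes$exons[[i]]
    type <- if (g$te_flag) "transposable_element" else "gene"
    parent <- GenomicRanges::GRanges(
      g$scaffold_id,
      IRanges::IRanges(g$start, g$end), strand = g$strand)
    S4Vectors::mcols(parent)$type <- type
    S4Vectors::mcols(parent)$ID <- g$gene_id
    if (!is.na(g$te_family)) S4Vectors::mcols(parent)$te_family <- g$te_family
    S4Vectors::mcols(parent)$est_support <- tolower(as.character(g$est_support))
    if (!is.na(g$protein_length))
      S4Vectors::mcols(parent)$protein_length <- as.character(g$protein_length)
    feats[[length(feats) + 1L]] <- parent
    if (!g$te_flag || nrow(ex) > 1) {
      kids <- GenomicRanges::GRanges(
        g$scaffold_id, IRanges::IRanges(ex$start, ex$end), strand = g$strand)
      S4Vectors::mcols(kids)$type <- "exon"
      S4Vectors::mcols(kids)$Parent <- g$gene_id
      feats[[length(feats) + 1L]] <- kids
    }
  }
  all <- suppressWarnings(do.call(c, lapply(feats, function(x) {
    ## harmonise metadata columns across feature chunks
    for (col in c("ID", "Parent", "te_family", "est_support", "protein_length"))
      if (!col %in% colnames(S4Vectors::mcols(x)))
        S4Vectors::mcols(x)[[col]] <- NA_character_
    x
  })))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a gene-homology table
#'
#' Expects a tab-separated file with a header line and four columns:
#' `gene_a`, `gene_b`, `identity` (percent) and `evalue`. Duplicate gene
#' pairs are collapsed keeping the best (smallest) e-value.
#'
#' @param path path to the TSV file.
#' @param strict if `TRUE`, malformed rows abort; otherwise they are
#'   skipped with a warning.
#' @return a data.frame with columns `gene_a`, `gene_b`, `identity`,
#'   `evalue`.
#' @export
read_homology_table <- function(path, strict = FALSE) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), evalue = numeric()))
  }
  if (ncol(raw) < 4) stop("homology table needs 4 columns", call. = FALSE)
  df <- data.frame(gene_a = as.character(raw[[1]]),
                   gene_b = as.character(raw[[2]]),
                   identity = suppressWarnings(as.numeric(raw[[3]])),
                   evalue = suppressWarnings(as.numeric(raw[[4]])),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$identity) | is.na(df$evalue) |
    df$identity < 0 | df$identity > 100 | !nzchar(df$gene_a) | !nzchar(df$gene_b)
  if (any(bad)) {
    if (strict) stop(sum(bad), " malformed homology row(s)", call. = FALSE)
    warning("skipping ", sum(bad), " malformed homology row(s)")
    df <- df[!bad, , drop = FALSE]
  }
  ## collapse duplicate pairs: keep minimal e-value, then maximal identity
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  df <- df[order(key, df$evalue, -df$identity), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene-homology table
#' @param df data.frame with columns `gene_a`, `gene_b`, `identity`, `evalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(df, path) {
  write.table(df[, c("gene_a", "gene_b", "identity", "evalue")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
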