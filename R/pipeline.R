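## End-to-end orchestration: simulate a BAC pool, run every analysis
## stage in dependency order and write the report files plus a run
## manifest. This is the programmatic equivalent of a subcommand driver;
## all thresholds live in one config object so report conventions are
## centralised.

#' Build a run configuration
#'
#' All tuning knobs of the pipeline with their package defaults.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stage seed is derived from it.
#' @param genome_length,gene_density,te_fraction,gc toy-genome
#'   parameters.
#' @param n_clones,insert_mean,insert_sd BAC-pool parameters.
#' @param n_gaps_per_scaffold scaffolding gaps per clone scaffold.
#' @param min_identity,min_len,window assignment floors and the
#'   junction search window.
#' @param evalue_cut,max_gap synteny knobs.
#' @param ssr_minima SSR minimum array lengths per unit length.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("bacpool_run_"), seed = 1L,
                       genome_length = 1e6, gene_density = 9.9,
                       te_fraction = 0.08, gc = 0.33,
                       n_clones = 4L, insert_mean = 139000,
                       insert_sd = 10000, n_gaps_per_scaffold = 7L,
                       min_identity = 95, min_len = 50L, window = 500L,
                       evalue_cut = 1e-46, max_gap = 3L,
                       ssr_minima = ssr_thresholds()) {
  cfg <- as.list(environment())
  stopifnot(genome_length > insert_mean + 3 * insert_sd, n_clones >= 1)
  class(cfg) <- "run_config"
  cfg
}

derive_seed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2000000000L

#' Run the full pipeline on simulated data
#'
#' Stages, in order: genome and pool simulation, per-clone scaffold
#' construction, assembly statistics, clone assignment, accuracy census
#' of the first clone against its pre-assembly reference, annotation/SSR
#' /TE census of the genome, and microsynteny analysis of a simulated
#' diverged region pair. Every output is a text file under
#' `config$out_dir`; a JSON manifest records the configuration, seeds
#' and file digests. Reruns with the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  genome <- make_genome(config$genome_length, config$gene_density,
                        config$te_fraction, config$gc,
                        seed = derive_seed(config$seed, 1L))
  pool <- make_bac_pool(genome, config$n_clones, config$insert_mean,
                        config$insert_sd, seed = derive_seed(config$seed, 2L))
  profile <- error_profile(seed = derive_seed(config$seed, 3L))
  scaffolds <- lapply(seq_along(pool$clones), function(i) {
    simulate_clone_scaffold(pool, pool$clones[[i]]$id,
                            n_gaps = config$n_gaps_per_scaffold,
                            profile = if (i == 1L) profile else NULL,
                            seed = derive_seed(config$seed, 10L + i))
  })
  scf_df <- data.frame(
    id = vapply(scaffolds, `[[`, character(1), "id"),
    sequence = vapply(scaffolds, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)

  write_fasta(scf_df, p("scaffolds.fasta"))
  write_fasta(pool$markers[, c("id", "sequence")], p("markers.fasta"))
  write_gene_models(genome$genes, p("genome_annotation.gff3"))
  write.table(pool$truth, p("truth_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  stats <- summarize_assembly(scf_df)
  write_assembly_report(stats, p("assembly_stats.tsv"))

  assignments <- assign_clones(scf_df, pool$clones, pool$markers,
                               pool$junctions,
                               min_identity = config$min_identity,
                               min_len = config$min_len,
                               window = config$window)
  write_assignments(assignments, p("assignments.tsv"))

  acc <- accuracy_report(scaffolds[[1]]$reference,
                         scaffolds[[1]]$sequence)
  write_accuracy_report(acc, p("accuracy.tsv"))

  gsum <- summarize_genes(genome$genes,
                          data.frame(id = "genome",
                                     sequence = genome$sequence,
                                     stringsAsFactors = FALSE))
  ssrs <- find_ssrs(genome$sequence, config$ssr_minima,
                    scaffold_id = "genome")
  ssum <- summarize_ssrs(ssrs, gsum$total_bp, gsum$non_n_bp)
  tsum <- summarize_tes(genome$genes, gsum$total_bp)
  write_ssr_bed(ssrs, p("ssrs.bed"))
  census <- data.frame(
    metric = c("Total sequence length", "Non-N length",
               "Protein coding genes", "EST supported (%)",
               "Gene density (/100kb)", "Average exon length",
               "Average intron length", "Exons per gene",
               "Average protein length", "GC (%)", "SSR count",
               "SSR bp", "SSR (%)", "kb per SSR", "TE copies", "TE bp",
               "TE (%)"),
    value = c(gsum$total_bp, gsum$non_n_bp, gsum$n_genes,
              gsum$est_support_pct, gsum$gene_density,
              round_half_up(gsum$mean_exon_bp, 0),
              round_half_up(gsum$mean_intron_bp, 0),
              round_half_up(gsum$exons_per_gene, 1),
              round_half_up(gsum$mean_protein_aa, 0),
              round_half_up(gsum$gc_percent, 1),
              ssum$count, ssum$bp, ssum$percent, ssum$kb_per_ssr,
              sum(tsum$classes$copies), sum(tsum$classes$total_bp),
              te_percent(sum(tsum$classes$total_bp), gsum$total_bp, 1)))
  write.table(census, p("annotation_census.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tsum$families[, c("family", "class", "copies", "total_bp",
                                "percent")],
              p("te_content.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  syn_genome <- make_genome(1e5, config$gene_density, 0.02, config$gc,
                            seed = derive_seed(config$seed, 4L))
  syn <- make_synteny_pair(syn_genome, seed = derive_seed(config$seed, 5L))
  syn_blocks <- analyze_synteny(syn$region_a$genes, syn$region_b$genes,
                                syn$homology,
                                evalue_cut = config$evalue_cut,
                                max_gap = config$max_gap)
  write.table(syn_blocks, p("synteny_blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  files <- c("scaffolds.fasta", "markers.fasta", "genome_annotation.gff3",
             "truth_table.tsv", "assembly_stats.tsv", "assignments.tsv",
             "accuracy.tsv", "annotation_census.tsv", "te_content.tsv",
             "ssrs.bed", "synteny_blocks.tsv")
  manifest <- list(
    package = "bacpool",
    version = as.character(utils::packageVersion("bacpool")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(genome = genome, pool = pool, scaffolds = scaffolds,
                 stats = stats, assignments = assignments, accuracy = acc,
                 gene_summary = gsum, ssr_summary = ssum,
                 te_summary = tsum, synteny = syn_blocks,
                 manifest = p("manifest.json")))
}
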