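test_that("make_genome honours density, GC and determinism", {
  g <- make_genome(100000, 10, 0.05, 0.33, seed = 1)
  n_genes <- sum(!g$genes$te_flag)
  expect_gte(n_genes, 8)
  expect_lte(n_genes, 12)
  g0 <- make_genome(10000, 0, 0, 0.5, seed = 7)
  expect_equal(nrow(g0$genes), 0)
  g2 <- make_genome(200000, 9.9, 0.08, 0.33, seed = 42)
  gcf <- sum(strsplit(g2$sequence, "")[[1]] %in% c("G", "C")) /
    nchar(g2$sequence)
  expect_gte(gcf, 0.31)
  expect_lte(gcf, 0.35)
  ## determinism: identical seeds give identical objects
  ga <- make_genome(50000, 10, 0.05, 0.33, seed = 5)
  gb <- make_genome(50000, 10, 0.05, 0.33, seed = 5)
  expect_identical(ga$sequence, gb$sequence)
  expect_identical(ga$genes$gene_id, gb$genes$gene_id)
  ## annotations lie within the sequence
  expect_true(all(g$genes$start >= 1 & g$genes$end <= nchar(g$sequence)))
  ## genes never overlap TEs
  gn <- g$genes[!g$genes$te_flag, ]
  te <- g$genes[g$genes$te_flag, ]
  for (i in seq_len(nrow(gn))) {
    expect_false(any(gn$start[i] <= te$end & gn$end[i] >= te$start))
  }
})

test_that("make_genome rejects impossible requests", {
  expect_error(make_genome(5000, 10, 0, 0.4, seed = 1))
})

test_that("BAC pool inserts are BamHI-delimited and truth round-trips", {
  g <- make_genome(400000, 8, 0.03, 0.33, seed = 2)
  pool <- make_bac_pool(g, 3, insert_mean = 90000, insert_sd = 5000,
                        seed = 4)
  expect_length(pool$clones, 3)
  expect_equal(nrow(pool$truth), 3)
  for (i in 1:3) {
    ins <- pool$inserts[[i]]
    expect_equal(substr(ins, 1, 6), "GGATCC")
    expect_equal(substr(ins, nchar(ins) - 5, nchar(ins)), "GGATCC")
    tr <- pool$truth[i, ]
    ## extracting via the truth table reproduces the stored insert
    expect_identical(substr(pool$genome_sequence, tr$start, tr$end), ins)
    expect_equal(tr$end - tr$start + 1, nchar(ins))
    cl <- pool$clones[[i]]
    expect_equal(nchar(cl$end_seqs$left), 500)
    expect_identical(cl$end_seqs$left, substr(ins, 1, 500))
    expect_identical(cl$end_seqs$right,
                     revcomp(substr(ins, nchar(ins) - 499, nchar(ins))))
  }
  ## single clone: exactly one truth interval
  p1 <- make_bac_pool(g, 1, insert_mean = 90000, insert_sd = 5000, seed = 9)
  expect_equal(nrow(p1$truth), 1)
  ## insert mean near the requested library mean
  expect_lt(abs(mean(nchar(pool$inserts)) - 90000), 3 * 5000 / sqrt(3))
  ## oversized insert request is rejected
  expect_error(make_bac_pool(g, 2, insert_mean = 390000, seed = 1),
               "insert_mean")
})

test_that("fragmentation conserves non-N content and places exact gaps", {
  set.seed(3)
  insert <- rand_dna(50000, 0.35)
  ## zero gaps: identity
  expect_identical(fragment_and_scaffold(insert, 0, seed = 1)$sequence,
                   insert)
  f <- fragment_and_scaffold(insert, 7, c(100, 2000), seed = 5)
  gs <- gap_stats(f$sequence)
  expect_equal(gs$n_stretches, 7)
  expect_equal(nchar(f$sequence), nchar(insert))
  expect_equal(nchar(f$sequence) - gs$total_gap_bp,
               nchar(insert) - sum(f$gaps$length))
  ## non-N content is a subsequence of the insert
  expect_identical(gsub("N", "", substr(f$sequence, 1, f$gaps$start[1] - 1)),
                   substr(insert, 1, f$gaps$start[1] - 1))
  ## a single fixed-size gap
  f1 <- fragment_and_scaffold(insert, 1, c(478, 478), seed = 2)
  expect_equal(gap_stats(f1$sequence)$stretches$length, 478)
  ## gaps that cannot fit are rejected
  expect_error(fragment_and_scaffold(rand_dna(1500), 3, c(400, 400),
                                     seed = 1), "ends")
})

test_that("error injection records events and spares short runs", {
  ## all-zero profile: identity
  p0 <- error_profile(0, run_length_threshold = 11,
                      dinucleotide_perturb_prob = 0, seed = 1)
  set.seed(4)
  s <- rand_dna(5000, 0.4)
  out0 <- inject_errors(s, p0)
  expect_identical(out0$sequence, s)
  expect_equal(nrow(out0$events), 0)
  ## forced contraction of a planted A14 run by exactly one base
  s14 <- paste0(substr(s, 1, 2000), "G", strrep("A", 14), "G",
                substr(s, 2001, 5000))
  p1 <- error_profile(1, c(1, 1), 11, 0, seed = 2)
  out1 <- inject_errors(s14, p1)
  expect_equal(nrow(out1$events), 1)
  expect_equal(out1$events$delta_bp, -1)
  expect_match(out1$sequence, "GAAAAAAAAAAAAAG")
  expect_false(grepl(strrep("A", 14), out1$sequence))
  ## runs shorter than the threshold are never modified
  p_all <- error_profile(1, c(1, 3), 11, 1, seed = 3)
  short <- paste0(substr(s, 1, 1000), "G", strrep("T", 10), "G",
                  substr(s, 1001, 3000))
  expect_false(any(inject_errors(short, p_all)$events$ref_len < 11))
})

test_that("synteny pairs conserve gene order and expand region A", {
  g <- make_genome(100000, 10, 0.02, 0.33, seed = 9)
  ## identity case
  syn0 <- make_synteny_pair(g, 0, 1.0, 0.0, seed = 1)
  expect_identical(syn0$region_a$sequence, syn0$region_b$sequence)
  expect_equal(nrow(syn0$homology), sum(!g$genes$te_flag))
  expect_true(all(syn0$homology$identity == 100))
  ## expanded case
  syn <- make_synteny_pair(g, 15, 1.3, 0.13, seed = 3)
  ratio <- nchar(syn$region_a$sequence) / nchar(syn$region_b$sequence)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.2)
  ## order and orientation conserved
  ga <- syn$region_a$genes[!syn$region_a$genes$te_flag, ]
  gb <- syn$region_b$genes[!syn$region_b$genes$te_flag, ]
  ga <- ga[order(ga$start), ]; gb <- gb[order(gb$start), ]
  expect_identical(sub("^a_", "", ga$gene_id), sub("^b_", "", gb$gene_id))
  expect_identical(ga$strand, gb$strand)
  ## divergence shows up as ~87% mean identity
  expect_gt(mean(syn$homology$identity), 84)
  expect_lt(mean(syn$homology$identity), 90)
})
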