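test_that("reciprocal-best pairing keeps mutual pairs only", {
  ga <- mk_genes(c("a1", "a2"), c(1, 3000))
  gb <- mk_genes(c("b1", "b2"), c(1, 3000))
  hom <- data.frame(gene_a = "a1", gene_b = "b1", identity = 90,
                    evalue = 1e-60)
  expect_equal(nrow(pair_homologs(ga, gb, hom)), 1)
  ## a1 best-hits b1 but b1 best-hits a2: reciprocity fails for a1
  tri <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b1"),
                    identity = c(90, 95), evalue = c(1e-60, 1e-80))
  pr <- pair_homologs(ga, gb, tri)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$gene_a, "a2")
  ## cuts are applied
  weak <- data.frame(gene_a = "a1", gene_b = "b1", identity = 90,
                     evalue = 1e-20)
  expect_equal(nrow(pair_homologs(ga, gb, weak)), 0)
  ## TE-flagged genes never pair
  gat <- mk_genes(c("a1", "a2"), c(1, 3000), te = c(FALSE, TRUE))
  tehom <- data.frame(gene_a = "a2", gene_b = "b1", identity = 90,
                      evalue = 1e-60)
  expect_equal(nrow(pair_homologs(gat, gb, tehom)), 0)
})

test_that("tandem arrays collapse to one representative", {
  g <- mk_genes(c("x1", "x2", "x3", "y1"), c(1, 2000, 4000, 9000))
  hom <- data.frame(gene_a = c("x1", "x2", "x1"),
                    gene_b = c("x2", "x3", "x3"),
                    identity = 92, evalue = 1e-70)
  coll <- collapse_tandem(g, hom)
  expect_equal(nrow(coll), 2)
  expect_equal(coll$array_size, c(3, 1))
  ## representative prefers the member with a cross-region pair
  pairs <- data.frame(gene_a = "x2", gene_b = "zz", identity = 90,
                      evalue = 1e-60)
  coll2 <- collapse_tandem(g, hom, pairs = pairs)
  expect_equal(coll2$gene_id[coll2$array_size == 3], "x2")
  ## adjacent non-homologous genes stay separate
  expect_equal(nrow(collapse_tandem(g, hom[0, ])), 4)
})

test_that("block finding respects the gap rule and ignores order", {
  ids_a <- sprintf("a%d", 1:15)
  ids_b <- sprintf("b%d", 1:15)
  ga <- mk_genes(ids_a, seq(1, by = 2000, length.out = 15))
  gb <- mk_genes(ids_b, seq(1, by = 2000, length.out = 15))
  ## all paired in order: one block
  hom_all <- data.frame(gene_a = ids_a[1:5], gene_b = ids_b[1:5],
                        identity = 90, evalue = 1e-60)
  pr <- pair_homologs(ga, gb, hom_all)
  bl <- find_blocks(ga, gb, pr)
  expect_length(bl, 1)
  expect_equal(nrow(bl[[1]]$pairs), 5)
  ## two clusters split by > max_gap unpaired genes
  hom_split <- data.frame(gene_a = ids_a[c(1, 2, 10, 11)],
                          gene_b = ids_b[c(1, 2, 10, 11)],
                          identity = 90, evalue = 1e-60)
  bl2 <- find_blocks(ga, gb, pair_homologs(ga, gb, hom_split))
  expect_length(bl2, 2)
  ## local inversion still forms one block
  hom_inv <- data.frame(gene_a = ids_a[1:4], gene_b = ids_b[c(1, 3, 2, 4)],
                        identity = 90, evalue = 1e-60)
  bl3 <- find_blocks(ga, gb, pair_homologs(ga, gb, hom_inv))
  expect_length(bl3, 1)
  expect_equal(nrow(bl3[[1]]$pairs), 4)
})

test_that("block finding agrees with exhaustive enumeration", {
  set.seed(24)
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    ids_a <- sprintf("a%d", seq_len(n))
    ids_b <- sprintf("b%d", seq_len(n))
    ga <- mk_genes(ids_a, seq(1, by = 2000, length.out = n))
    gb <- mk_genes(ids_b, seq(1, by = 2000, length.out = n))
    k <- sample(2:min(5, n), 1)
    ia <- sort(sample(n, k))
    ib <- sample(sort(sample(n, k)))
    hom <- data.frame(gene_a = ids_a[ia], gene_b = ids_b[ib],
                      identity = 90, evalue = 1e-60)
    pr <- pair_homologs(ga, gb, hom)
    mine <- find_blocks(ga, gb, pr, max_gap = 2)
    ## oracle works on A-sorted pair indices
    ia2 <- match(pr$gene_a, ids_a); ib2 <- match(pr$gene_b, ids_b)
    ord <- order(ia2)
    orc <- oracle_blocks(ia2[ord], ib2[ord],
                         seq_len(n) %in% ia2, seq_len(n) %in% ib2,
                         max_gap = 2)
    expect_length(mine, length(orc))
    if (length(mine)) {
      expect_equal(lapply(mine, function(b) nrow(b$pairs)),
                   lapply(orc, function(x) x[2] - x[1] + 1L))
    }
  }
})

test_that("syntenic quality equals the hand-computed formula", {
  ## 4 conserved of 5 countable on each side -> 80.0
  ids_a <- sprintf("a%d", 1:5); ids_b <- sprintf("b%d", 1:5)
  ga <- mk_genes(ids_a, seq(1, by = 2000, length.out = 5))
  gb <- mk_genes(ids_b, seq(1, by = 2000, length.out = 5))
  hom <- data.frame(gene_a = ids_a[c(1, 2, 3, 5)],
                    gene_b = ids_b[c(1, 2, 3, 5)],
                    identity = 90, evalue = 1e-60)
  pr <- pair_homologs(ga, gb, hom)
  bl <- find_blocks(ga, gb, pr)
  q <- synteny_quality(bl[[1]], ga, gb, hom)
  expect_equal(q$quality, 80)
  expect_equal(c(q$total_a, q$total_b), c(5, 5))
  ## all conserved -> 100
  hom_all <- data.frame(gene_a = ids_a, gene_b = ids_b, identity = 90,
                        evalue = 1e-60)
  pr2 <- pair_homologs(ga, gb, hom_all)
  q2 <- synteny_quality(find_blocks(ga, gb, pr2)[[1]], ga, gb, hom_all)
  expect_equal(q2$quality, 100)
  ## region A: 6 entries incl 1 TE and a 2-copy tandem -> 4 countable;
  ## B: 4 countable; 3 pairs -> 100*(3+3)/(4+4) = 75.0
  ga3 <- mk_genes(c("a1", "a2", "a2b", "a3", "a4", "ate"),
                  c(1, 2000, 4000, 6000, 8000, 10000),
                  te = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  gb3 <- mk_genes(c("b1", "b2", "b3", "b4"),
                  c(1, 2000, 4000, 6000))
  hom3 <- rbind(
    data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"),
               identity = 90, evalue = 1e-60),
    data.frame(gene_a = "a2", gene_b = "a2b", identity = 95,
               evalue = 1e-90))   # same-side tandem link
  pr3 <- pair_homologs(ga3, gb3, hom3[hom3$gene_b %in% gb3$gene_id, ])
  bl3 <- find_blocks(ga3, gb3, pr3)
  ## extend the block to the full regions by hand for the formula check
  blk <- list(pairs = pr3, a_genes = ga3$gene_id, b_genes = gb3$gene_id)
  q3 <- synteny_quality(blk, ga3, gb3, hom3)
  expect_equal(q3$quality, 75)
  expect_equal(c(q3$total_a, q3$total_b), c(4, 4))
})

test_that("quality is monotone in unpaired genes and blind to TEs", {
  ids_a <- sprintf("a%d", 1:4); ids_b <- sprintf("b%d", 1:4)
  ga <- mk_genes(ids_a, seq(1, by = 2000, length.out = 4))
  gb <- mk_genes(ids_b, seq(1, by = 2000, length.out = 4))
  hom <- data.frame(gene_a = ids_a, gene_b = ids_b, identity = 90,
                    evalue = 1e-60)
  pr <- pair_homologs(ga, gb, hom)
  base <- synteny_quality(list(pairs = pr, a_genes = ids_a,
                               b_genes = ids_b), ga, gb, hom)$quality
  ## an extra unpaired non-TE gene lowers quality
  ga_plus <- mk_genes(c(ids_a, "a_extra"),
                      c(seq(1, by = 2000, length.out = 4), 9000))
  lower <- synteny_quality(list(pairs = pr,
                                a_genes = c(ids_a, "a_extra"),
                                b_genes = ids_b), ga_plus, gb, hom)$quality
  expect_lt(lower, base)
  ## an extra TE leaves quality unchanged
  ga_te <- mk_genes(c(ids_a, "a_te"),
                    c(seq(1, by = 2000, length.out = 4), 9000),
                    te = c(rep(FALSE, 4), TRUE))
  same <- synteny_quality(list(pairs = pr, a_genes = c(ids_a, "a_te"),
                               b_genes = ids_b), ga_te, gb, hom)$quality
  expect_equal(same, base)
})

test_that("structural ratios average per-pair values", {
  ex_a <- list(data.frame(start = c(1, 300, 700),
                          end = c(100, 400, 820)))      # introns 199, 299
  ex_b <- list(data.frame(start = c(1, 200, 500),
                          end = c(100, 300, 620)))      # introns 99, 199
  ga <- mk_genes("a1", 1, protein = 480L, exons = ex_a)
  gb <- mk_genes("b1", 1, protein = 500L, exons = ex_b)
  pr <- data.frame(gene_a = "a1", gene_b = "b1", identity = 90,
                   evalue = 1e-60)
  r <- ratio_stats(pr, ga, gb)
  expect_equal(r$protein_length_ratio, 0.96)
  expect_equal(r$exon_count_ratio, 1)
  expect_equal(r$mean_intron_ratio,
               round(mean(c(199, 299)) / mean(c(99, 199)), 2))
  ## identical models -> all ratios 1
  r2 <- ratio_stats(pr, gb <- mk_genes("a1", 1, protein = 500L,
                                       exons = ex_b),
                    mk_genes("b1", 1, protein = 500L, exons = ex_b))
  expect_equal(r2$protein_length_ratio, 1)
  expect_equal(r2$mean_intron_ratio, 1)
})

test_that("simulated diverged pairs recover quality 100 and the intron scale", {
  g <- make_genome(100000, 10, 0.02, 0.33, seed = 25)
  syn <- make_synteny_pair(g, te_insertions = 15, intron_scale = 1.3,
                           divergence = 0.13, seed = 26)
  res <- analyze_synteny(syn$region_a$genes, syn$region_b$genes,
                         syn$homology)
  expect_true(all(res$quality == 100))
  expect_true(all(abs(res$mean_intron_ratio - 1.3) <= 0.1))
  ## deleting genes from one side gives the hand-computed value
  ga <- syn$region_a$genes
  drop <- ga$gene_id[!ga$te_flag][1:2]
  hom2 <- syn$homology[!(syn$homology$gene_a %in% drop), ]
  ga2 <- ga[!(ga$gene_id %in% drop), ]
  res2 <- analyze_synteny(ga2, syn$region_b$genes, hom2)
  tot_a <- sum(res2$total_a); tot_b <- sum(res2$total_b)
  cons <- sum(res2$conserved_a) + sum(res2$conserved_b)
  expect_equal(sum(res2$quality * (res2$total_a + res2$total_b)) /
                 (tot_a + tot_b),
               100 * cons / (tot_a + tot_b), tolerance = 0.01)
})
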