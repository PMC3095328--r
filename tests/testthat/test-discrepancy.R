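test_that("a contracted homopolymer is classified with its length change", {
  set.seed(12)
  ctx <- rand_dna(2000, 0.4)
  ref <- paste0(substr(ctx, 1, 800), "G", strrep("A", 14), "G",
                substr(ctx, 801, 2000))
  test <- paste0(substr(ctx, 1, 800), "G", strrep("A", 13), "G",
                 substr(ctx, 801, 2000))
  r <- classify_discrepancies(align_locus(ref, test))
  expect_equal(nrow(r), 1)
  expect_equal(r$kind, "homopolymer")
  expect_equal(r$ref_len, 14)
  expect_equal(r$test_len, 13)
  expect_equal(r$delta_bp, -1)
  expect_equal(r$test_motif, "(A)_13")
})

test_that("a perturbed dinucleotide array yields one repeat record", {
  set.seed(13)
  ctx <- rand_dna(2200, 0.45)
  ref <- paste0(substr(ctx, 1, 1000), "TT", strrep("GA", 21), "TT",
                substr(ctx, 1001, 2200))
  ## expansion interrupted by an N stretch, as assemblies produce
  test <- paste0(substr(ctx, 1, 1000), "TT", strrep("GA", 21),
                 "GTAGTACGTAC", strrep("N", 23), "C", strrep("GA", 6),
                 "TT", substr(ctx, 1001, 2200))
  r <- classify_discrepancies(align_locus(ref, test))
  expect_equal(sum(r$kind == "dinucleotide_repeat"), 1)
  expect_equal(r$ref_motif[r$kind == "dinucleotide_repeat"], "(GA)_21")
  ## plain unit loss
  test2 <- paste0(substr(ctx, 1, 1000), "TT", strrep("GA", 19), "TT",
                  substr(ctx, 1001, 2200))
  r2 <- classify_discrepancies(align_locus(ref, test2))
  expect_equal(r2$kind, "dinucleotide_repeat")
  expect_equal(r2$delta_bp, -4)
})

test_that("isolated mismatches are substitutions", {
  set.seed(14)
  ref <- rand_dna(1500, 0.4)
  ch <- strsplit(ref, "")[[1]]
  ch[700] <- setdiff(c("A", "C", "G", "T"), ch[700])[1]
  r <- classify_discrepancies(align_locus(ref, paste(ch, collapse = "")))
  expect_equal(r$kind, "substitution")
  expect_equal(r$ref_pos, 700)
})

test_that("run census counts maximal runs and joins discrepancies", {
  cen <- run_census("GGGGGTTTTTTTCAAAAAA",
                    data.frame(kind = character(), ref_pos = integer(),
                               ref_motif = character(), ref_len = integer(),
                               test_motif = character(),
                               test_len = integer(), delta_bp = integer()),
                    min_run = 5)
  expect_equal(cen$count[cen$class == "A/T" & cen$length == 7], 1)
  expect_equal(cen$count[cen$class == "A/T" & cen$length == 6], 1)
  expect_equal(cen$count[cen$class == "C/G" & cen$length == 5], 1)
  expect_true(all(cen$discrepant == 0))
  ## records referencing absent runs are an error
  bad <- data.frame(kind = "homopolymer", ref_pos = 999L,
                    ref_motif = "(A)_12", ref_len = 12L,
                    test_motif = "(A)_11", test_len = 11L, delta_bp = -1L)
  expect_error(run_census("GGGGGTTTTTTT", bad), "absent")
})

test_that("census recovery: planted events only, nothing below threshold", {
  g <- make_genome(60000, 8, 0.03, 0.33, seed = 15)
  ref <- g$sequence
  prof <- error_profile(seed = 16)
  inj <- inject_errors(ref, prof)
  r <- classify_discrepancies(align_locus(ref, inj$sequence))
  expect_equal(sum(r$kind == "homopolymer"),
               sum(inj$events$type == "homopolymer"))
  expect_equal(sum(r$kind == "dinucleotide_repeat"),
               sum(inj$events$type == "dinucleotide"))
  expect_equal(sum(!r$kind %in% c("homopolymer", "dinucleotide_repeat",
                                  "n_gap_excluded")), 0)
  expect_setequal(r$ref_pos[r$kind == "homopolymer"],
                  inj$events$pos[inj$events$type == "homopolymer"])
  ## the profile only touches runs >= 11, so lengths <= 10 stay clean
  cen <- run_census(ref, r)
  expect_true(all(cen$discrepant[cen$length <= 10] == 0))
  ## conservation: census counts match per-length planted counts
  hp <- inj$events[inj$events$type == "homopolymer", ]
  for (L in unique(hp$ref_len)) {
    expect_equal(sum(cen$discrepant[cen$length == L]), sum(hp$ref_len == L))
  }
})

test_that("discrepancy rate arithmetic rounds half-up at one decimal", {
  expect_equal(discrepancy_rate(17, 98716), 1.7)
  expect_equal(discrepancy_rate(0, 10000), 0)
  expect_equal(discrepancy_rate(5, 10000), 5)
  ## only the two repeat classes count from a record table
  recs <- data.frame(
    kind = c(rep("homopolymer", 3), "dinucleotide_repeat", "substitution",
             "other_indel", "n_gap_excluded"),
    ref_pos = 1:7, ref_motif = NA, ref_len = 1, test_motif = NA,
    test_len = 1, delta_bp = 0)
  expect_equal(discrepancy_rate(recs, 20000), 2)
})

test_that("accuracy_report assembles the census end to end", {
  set.seed(17)
  ctx <- rand_dna(9500, 0.4)
  ref <- paste0(substr(ctx, 1, 4000), "C", strrep("T", 12), "C",
                substr(ctx, 4001, 9500))
  test <- paste0(substr(ctx, 1, 2000), strrep("N", 150),
                 substr(ctx, 2151, 4000), "C", strrep("T", 11), "C",
                 substr(ctx, 4001, 9500))
  rep <- accuracy_report(ref, test)
  expect_equal(rep$ref_length, nchar(ref))
  expect_equal(rep$n_stretches, 1)
  expect_equal(rep$n_stretch_bp, 150)
  expect_equal(rep$homopolymer_discrepancies, 1)
  expect_equal(rep$rate_per_10kb, discrepancy_rate(1, nchar(ref)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_accuracy_report(rep, f)
  expect_true(any(grepl("Stretches of Ns", readLines(f))))
})
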