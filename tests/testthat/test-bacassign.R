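make_scaffold_set <- function(seed = 18, n = 3, len = 20000) {
  set.seed(seed)
  data.frame(id = sprintf("scf%d", seq_len(n)),
             sequence = vapply(seq_len(n), function(i) rand_dna(len, 0.4),
                               character(1)),
             stringsAsFactors = FALSE)
}

test_that("exact markers hit once; absent markers do not hit", {
  scf <- make_scaffold_set()
  mk <- data.frame(id = c("m1", "m_absent"),
                   sequence = c(substr(scf$sequence[2], 5000, 5299),
                                rand_dna(300, 0.4)),
                   stringsAsFactors = FALSE)
  hits <- find_marker_hits(mk, scf)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$scaffold_id, "scf2")
  expect_equal(hits$identity, 100)
  expect_equal(hits$start, 5000)
})

test_that("duplicated marker loci keep the best hit and log ambiguity", {
  scf <- make_scaffold_set()
  marker <- substr(scf$sequence[1], 8000, 8299)
  ## plant a 97%-identity copy of the marker on scf3
  degraded <- strsplit(marker, "")[[1]]
  mut <- seq(5, 295, by = 34)
  degraded[mut] <- vapply(degraded[mut], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  scf$sequence[3] <- paste0(substr(scf$sequence[3], 1, 4000),
                            paste(degraded, collapse = ""),
                            substr(scf$sequence[3], 4301, nchar(scf$sequence[3])))
  hits <- find_marker_hits(data.frame(id = "m1", sequence = marker), scf)
  expect_equal(hits$scaffold_id, "scf1")
  expect_equal(hits$identity, 100)
})

test_that("junction hits are found at extremes on both strands", {
  j <- default_junctions()
  set.seed(19)
  core <- rand_dna(5000, 0.4)
  scf <- data.frame(
    id = c("starts_with_left", "rc_right_at_end", "no_junction"),
    sequence = c(paste0(j$left, core),
                 paste0(core, revcomp(j$right)),
                 core),
    stringsAsFactors = FALSE)
  b <- find_borders(scf, NULL, j$left, j$right)
  b1 <- b[b$scaffold_id == "starts_with_left", ]
  expect_equal(b1$side, "left")
  expect_equal(b1$method, "junction_at_extreme")
  expect_equal(b1$position, 0)
  expect_equal(b1$strand, "+")
  b2 <- b[b$scaffold_id == "rc_right_at_end", ]
  expect_equal(b2$side, "right")
  expect_equal(b2$position, 0)
  expect_equal(b2$strand, "-")
  expect_equal(nrow(b[b$scaffold_id == "no_junction", ]), 0)
})

test_that("junction reads place borders (mode 2)", {
  j <- default_junctions()
  set.seed(20)
  core <- rand_dna(4000, 0.4)
  scf <- data.frame(id = "s", sequence = core)
  read <- paste0(j$left, substr(core, 1, 200))
  b <- find_borders(scf, NULL, j$left, j$right, reads = read)
  expect_equal(b$method, "read_with_junction")
  expect_equal(b$side, "left")
})

test_that("BAC-end hits count found ends (mode 3)", {
  set.seed(21)
  core <- rand_dna(120000, 0.4)
  scf <- data.frame(id = "s", sequence = core)
  clone <- list(id = "c1", marker_ids = character(0),
                end_seqs = list(left = substr(core, 1, 500),
                                right = revcomp(substr(core, 119501, 120000))))
  b <- find_borders(scf, list(clone), default_junctions()$left,
                    default_junctions()$right)
  ends <- b[b$method == "bac_end_blast", ]
  expect_equal(nrow(ends), 2)
  expect_setequal(ends$side, c("left", "right"))
  expect_equal(ends$clone_id, c("c1", "c1"))
})

test_that("completeness classification is total and follows the rules", {
  expect_equal(classify_completeness(2, 151031, TRUE), "complete")
  expect_equal(classify_completeness(2, 151031, FALSE), "complete")
  expect_equal(classify_completeness(1, 105000, FALSE), "likely_complete")
  expect_equal(classify_completeness(1, 80000, FALSE), "partial")
  expect_equal(classify_completeness(1, 60000, TRUE), "partial")
  expect_equal(classify_completeness(0, 10343, TRUE), "fragmentary")
  expect_equal(classify_completeness(0, 10343, FALSE), "unassigned")
  ## every evidence combination maps to exactly one label
  grid <- expand.grid(ends = 0:2, len = c(1e3, 6e4, 8e4, 1e5 + 1, 2e5),
                      marker = c(TRUE, FALSE))
  labs <- classify_completeness(grid$ends, grid$len, grid$marker)
  expect_true(all(labs %in% c("complete", "likely_complete", "partial",
                              "fragmentary", "unassigned")))
  expect_length(labs, nrow(grid))
})

test_that("superscaffold gap arithmetic hits the target or the floor", {
  ss <- superscaffold(data.frame(scaffold_id = c("a", "b"),
                                 length = c(50000, 40000)), 100000)
  expect_equal(ss$inserted_gap_bp, 10000)
  expect_equal(ss$final_length, 100000)
  ## the arithmetic behind a 12,064 N manual gap
  ss2 <- superscaffold(data.frame(scaffold_id = c("a", "b"),
                                  length = c(60000, 66858)), 138922)
  expect_equal(ss2$inserted_gap_bp, 138922 - 126858)
  ## floor rule with warning when parts exceed the target
  expect_warning(
    ss3 <- superscaffold(data.frame(scaffold_id = c("a", "b"),
                                    length = c(70000, 70000)), 139000),
    "minimum")
  expect_equal(ss3$inserted_gap_bp, 100)
  ## sequence assembly respects orientation
  seqs <- c(a = "ACGTACGTGG", b = "TTTTGGGGCC")
  ss4 <- superscaffold(data.frame(scaffold_id = c("a", "b"),
                                  length = c(10, 10),
                                  orientation = c("+", "-")),
                       120, sequences = seqs)
  expect_equal(nchar(ss4$sequence), 120)
  expect_match(ss4$sequence, paste0("^ACGTACGTGG", "N+",
                                    revcomp("TTTTGGGGCC"), "$"))
  expect_error(superscaffold(data.frame(scaffold_id = "a", length = 10),
                             100))
})

test_that("whole pools are assigned back to their truth scaffolds", {
  g <- make_genome(400000, 8, 0.03, 0.33, seed = 22)
  pool <- make_bac_pool(g, 3, insert_mean = 90000, insert_sd = 5000,
                        seed = 23)
  scfs <- lapply(pool$clones, function(cl)
    simulate_clone_scaffold(pool, cl$id, n_gaps = 5,
                            seed = 100 + match(cl$id, pool$truth$clone_id)))
  scf_df <- data.frame(id = vapply(scfs, `[[`, character(1), "id"),
                       sequence = vapply(scfs, `[[`, character(1),
                                         "sequence"),
                       stringsAsFactors = FALSE)
  asg <- assign_clones(scf_df, pool$clones, pool$markers, pool$junctions)
  expect_equal(asg$scaffold_ids, paste0("scf_", asg$clone_id))
  expect_true(all(asg$ends_found == 2))
  expect_true(all(asg$completeness == "complete"))
})
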