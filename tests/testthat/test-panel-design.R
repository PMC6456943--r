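test_that("hamming distance counts mismatching positions", {
  expect_equal(hamming("ACGT", "ACGT"), 0)
  expect_equal(hamming("ACGT", "ACGA"), 1)
  expect_error(hamming("ACG", "ACGT"), "equal length")
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
      y <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
      expect_equal(hamming(x, y), oracle_hamming(x, y))
    }
  })
})

test_that("non-overlapping residues stay separate entities and are conserved", {
  sim <- simulate_panel(sim_config(n_residues = 10, flank_len = 40, seed = 3))
  pan <- preprocess_panel(sim$residues, seed = 1)
  expect_equal(nrow(pan$entities), 10)
  expect_equal(nrow(pan$discarded), 0)
  expect_equal(pan$n_residues + nrow(pan$discarded), pan$n_input)
  expect_setequal(c(pan$residues$residue_id, pan$discarded$residue_id),
                  sim$residues$id)
})

test_that("identical in-range overlaps merge; mismatched or long overlaps discard one", {
  cfg <- sim_config(n_residues = 1, flank_len = 650, seed = 7)
  sim <- simulate_panel(cfg, forced_overlap = c("merge", "mismatch", "long"))
  pan <- preprocess_panel(sim$residues, seed = 42)
  # merge pair: one entity holding both residues, extended sequence
  merged <- dplyr::count(pan$residues, entity_id)
  expect_true(any(merged$n == 2))
  ent2 <- merged$entity_id[merged$n == 2][1]
  ent_seq <- pan$entities$sequence[pan$entities$entity_id == ent2]
  expect_equal(nchar(ent_seq), 2 * 1301 - 120)
  offs <- sort(pan$residues$offset[pan$residues$entity_id == ent2])
  expect_equal(diff(offs), 1301 - 120)
  # the mismatch and long-overlap pairs each lose one residue
  expect_equal(sort(unique(pan$discarded$reason)),
               c("overlap_mismatch", "overlap_too_long"))
  expect_equal(nrow(pan$discarded), 2)
  expect_equal(pan$n_residues + nrow(pan$discarded), pan$n_input)
  # every input residue appears exactly once across entities + discarded
  expect_setequal(c(pan$residues$residue_id, pan$discarded$residue_id), sim$residues$id)
  expect_equal(anyDuplicated(c(pan$residues$residue_id, pan$discarded$residue_id)), 0)
})

test_that("k-merization partitions windows into SNP set A and background B", {
  seq30 <- "ACGTACGGTACCATGAGTTCAGGCATCAAT"
  pan <- make_panel(
    c(e1 = seq30),
    tibble::tibble(entity_id = "e1", residue_id = "r1", offset = 15L,
                   ref = substr(seq30, 16, 16), alt = "C")
  )
  ks <- kmerize_panel(pan, 10)
  expect_equal(nrow(ks$set_a), 2 * 10)
  # oracle: windows of a 30 bp sequence not covering offset 15
  orc <- oracle_kmer_sets(pan, 10)
  expect_equal(sort(ks$set_b$seq), sort(orc$B))
  expect_equal(sort(ks$set_a$seq), sort(vapply(orc$A, function(x) x$seq, "")))
  # K = 1: set A is exactly the two allele bases
  k1 <- kmerize_panel(pan, 1)
  expect_setequal(k1$set_a$seq, c(substr(seq30, 16, 16), "C"))
  # entity without residues contributes only background
  pan0 <- make_panel(c(e1 = seq30),
                     tibble::tibble(entity_id = character(0), residue_id = character(0),
                                    offset = integer(0), ref = character(0), alt = character(0)))
  k0 <- kmerize_panel(pan0, 10)
  expect_equal(nrow(k0$set_a), 0)
  expect_equal(nrow(k0$set_b), length(unique(str_windows <- sapply(0:20, function(s) substr(seq30, s + 1, s + 10)))))
  # K larger than the entity errors naming it
  expect_error(kmerize_panel(pan, 31), "e1")
  # residue too close to an edge
  pan_edge <- make_panel(
    c(e1 = seq30),
    tibble::tibble(entity_id = "e1", residue_id = "r1", offset = 2L,
                   ref = substr(seq30, 3, 3), alt = "A")
  )
  expect_error(kmerize_panel(pan_edge, 10), "end")
})

test_that("PDT conditions match the all-pairs brute-force verdict", {
  # hand-built failure: two residues with identical k-mers at some window
  s <- "TTTTTGAAACCGTTTTT"
  pan_dup <- make_panel(
    c(e1 = s, e2 = s),
    tibble::tibble(entity_id = c("e1", "e2"), residue_id = c("r1", "r2"),
                   offset = c(8L, 8L), ref = substr(s, 9, 9), alt = c("T", "T"))
  )
  ks <- kmerize_panel(pan_dup, 6)
  chk <- check_pdt_conditions(ks, 0)
  expect_false(chk$ok)
  expect_true(all(chk$violations$dist == 0))

  # seeded random instances agree with the naive oracle at several PDTs
  for (seed in c(2, 9)) {
    res <- random_panel_residues(2, flank = 12, seed = seed)
    pan <- preprocess_panel(res, seed = 1)
    for (pdt in 0:2) {
      for (k in (pdt + 1):10) {
        ks <- kmerize_panel(pan, k)
        expect_equal(check_pdt_conditions(ks, pdt)$ok, oracle_pdt_ok(pan, k, pdt),
                     info = sprintf("seed %d k %d pdt %d", seed, k, pdt))
      }
    }
  }
})

test_that("find_min_k matches exhaustive search and respects its contracts", {
  res <- random_panel_residues(1, flank = 30, seed = 5)
  pan <- preprocess_panel(res, seed = 1)
  d0 <- find_min_k(pan, pdt = 0, k_cap = 25)
  expect_equal(d0$k, oracle_min_k(pan, 0))
  expect_true(check_pdt_conditions(d0$kmer_sets, 0)$ok)
  if (d0$k > 1) {
    expect_gt(nrow(d0$violations_at_k_minus_1), 0)
    expect_false(check_pdt_conditions(kmerize_panel(pan, d0$k - 1), 0)$ok)
  }
  # indistinguishable loci: identical flanks never pass
  res2 <- random_panel_residues(1, flank = 20, seed = 8)
  twin <- res2
  twin$id <- "r99"; twin$pos <- res2$pos + 1000000L
  pan_twin <- preprocess_panel(dplyr::bind_rows(res2, twin), seed = 1)
  expect_error(find_min_k(pan_twin, pdt = 0, k_cap = 15), "redesign")
})
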