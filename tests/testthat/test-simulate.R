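test_that("the simulator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_residues = 5, flank_len = 30, read_len = 40, depth = 4, seed = 99)
  s1 <- simulate_panel(cfg); s2 <- simulate_panel(cfg)
  expect_identical(s1$residues, s2$residues)
  expect_identical(s1$truth, s2$truth)
  p1 <- preprocess_panel(s1$residues, seed = 1)
  r1 <- simulate_reads(p1, s1$truth, cfg)
  r2 <- simulate_reads(p1, s2$truth, cfg)
  expect_identical(r1, r2)
  s3 <- simulate_panel(sim_config(n_residues = 5, flank_len = 30, seed = 100))
  expect_false(identical(s1$residues$flank5, s3$residues$flank5))
})

test_that("flank base composition is close to uniform", {
  sim <- simulate_panel(sim_config(n_residues = 10, flank_len = 650, seed = 12))
  bases <- strsplit(paste0(sim$residues$flank5, sim$residues$flank3, collapse = ""), "")[[1]]
  tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-6)
})

test_that("read simulation hits the configured depth and carries planted alleles", {
  cfg <- sim_config(n_residues = 4, flank_len = 200, read_len = 80, depth = 8,
                    substitution_prob = 1, seed = 13)
  sim <- simulate_panel(cfg)
  pan <- preprocess_panel(sim$residues, seed = 1)
  reads <- simulate_reads(pan, sim$truth, cfg)
  len <- nchar(pan$entities$sequence[1])
  per_ent <- dplyr::count(reads, entity_id)
  cov <- per_ent$n * cfg$read_len / len
  expect_true(all(abs(cov - cfg$depth) / cfg$depth < 0.15))
  # substitution_prob = 1: every residue planted alt, every covering read shows it
  expect_true(all(sim$truth$planted_allele == "alt"))
  one <- pan$residues[1, ]
  cover <- reads[reads$entity_id == one$entity_id &
                 reads$start <= one$offset &
                 reads$start + cfg$read_len - 1 >= one$offset, ]
  expect_gt(nrow(cover), 0)
  seen <- vapply(seq_len(nrow(cover)), function(i) {
    idx <- if (cover$strand[i] == "+") one$offset - cover$start[i] + 1 else
      cfg$read_len - (one$offset - cover$start[i])
    base <- substr(cover$seq[i], idx, idx)
    if (cover$strand[i] == "-") base <- chartr("ACGT", "TGCA", base)
    base
  }, "")
  expect_true(all(seen == one$alt))
  # depth 0 gives no reads
  cfg0 <- sim_config(n_residues = 2, flank_len = 100, read_len = 50, depth = 0, seed = 1)
  sim0 <- simulate_panel(cfg0)
  pan0 <- preprocess_panel(sim0$residues, seed = 1)
  expect_equal(nrow(simulate_reads(pan0, sim0$truth, cfg0)), 0)
})

test_that("deviation injection is controlled, recorded and distance-respecting", {
  cfg <- sim_config(n_residues = 2, flank_len = 60, read_len = 50, paired = FALSE,
                    depth = 4, seed = 14)
  sim <- simulate_panel(cfg)
  pan <- preprocess_panel(sim$residues, seed = 1)
  reads <- simulate_reads(pan, sim$truth, cfg)
  none <- inject_deviations(reads, pan, count_per_read = 0, seed = 1)
  expect_identical(none$seq, reads$seq)
  mut <- inject_deviations(reads, pan, count_per_read = 2,
                           min_distance_from_snp = 10, seed = 2)
  mut2 <- inject_deviations(reads, pan, count_per_read = 2,
                            min_distance_from_snp = 10, seed = 2)
  expect_identical(mut$seq, mut2$seq)
  offs <- setNames(pan$residues$offset, pan$residues$entity_id)
  for (i in seq_len(nrow(mut))) {
    devs <- mut$deviations[[i]]
    expect_lte(length(devs), 2)
    if (length(devs) > 0) {
      expect_true(all(abs(devs - offs[[mut$entity_id[i]]]) >= 10))
      expect_false(identical(mut$seq[i], reads$seq[i]))
      expect_equal(sum(strsplit(mut$seq[i], "")[[1]] != strsplit(reads$seq[i], "")[[1]]),
                   length(devs))
    }
  }
})

test_that("FASTQ round-trips through the paired writer", {
  cfg <- sim_config(n_residues = 2, flank_len = 120, read_len = 60, depth = 3, seed = 15)
  sim <- simulate_panel(cfg)
  pan <- preprocess_panel(sim$residues, seed = 1)
  reads <- simulate_reads(pan, sim$truth, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1, f2)
  back <- read_fastq(c(f1, f2))
  expect_setequal(back$seq, reads$seq)
  expect_equal(nrow(back), nrow(reads))
})
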