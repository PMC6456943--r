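# Protocol steps are exercised against the plaintext backend (exact slot
# arithmetic), with a small RLWE cross-check at the end; the full-scale
# backend equivalence lives in the acceptance suite.

mini_design <- function(seed = 21, n = 2, flank = 20, pdt = 0) {
  res <- random_panel_residues(n, flank = flank, seed = seed)
  pan <- preprocess_panel(res, seed = 1)
  list(panel = pan, design = find_min_k(pan, pdt = pdt, k_cap = 20))
}

test_that("step 1 rotation flags block agreement in the batch slots", {
  md <- mini_design()
  plan <- protocol_plan(md$design, l = 2, n_batch = 4)
  pb <- plaintext_backend(plan$spec$slots)
  km <- plan$groups$kmers[[1]][1]          # a panel k-mer as the user k-mer
  enc <- encrypt_user_kmers(km, plan, pb)
  codes <- plan$groups$codes[[1]][, 1]
  for (b in seq_len(plan$spec$b)) {
    rot <- step1_rotate(pb, enc$batches[[1]][[b]], codes[b], plan$spec$n_batch)
    expect_equal(he_decrypt(pb, rot)[1], 1)   # slot n = 0 flags agreement
    if (codes[b] == 0) expect_equal(rot$v, enc$batches[[1]][[b]]$v)  # rotation by 0
  }
})

test_that("step 2 products AND the blocks; step 3 counts group matches", {
  pb <- plaintext_backend(64)
  withr::with_seed(31, {
    for (i in 1:10) {
      vs <- replicate(3, sample(0:1, 64, TRUE), simplify = FALSE)
      cts <- lapply(vs, he_encrypt, backend = pb)
      d <- step2_block_product(pb, cts)
      expect_equal(he_decrypt(pb, d), Reduce(`*`, vs))
    }
  })
  expect_equal(he_decrypt(pb, step2_block_product(pb, list(he_encrypt(pb, c(1, 0, 1))))),
               c(1, 0, 1, rep(0, 61)))
  # step 3: empty group is zero; sums are slotwise
  expect_equal(he_decrypt(pb, step3_sum(pb, list())), rep(0, 64))
  a <- he_encrypt(pb, c(1, rep(0, 63))); b <- he_encrypt(pb, c(1, 1, rep(0, 62)))
  expect_equal(he_decrypt(pb, step3_sum(pb, list(a, b)))[1:3], c(2, 1, 0))
})

test_that("a duplicated panel k-mer drives a slot count of 2 (assumption failure mode)", {
  md <- mini_design()
  plan <- protocol_plan(md$design, l = 2, n_batch = 4)
  pb <- plaintext_backend(plan$spec$slots)
  km <- plan$groups$kmers[[1]][1]
  # duplicate the k-mer inside the group's codes
  plan$groups$codes[[1]] <- cbind(plan$groups$codes[[1]][, 1],
                                  plan$groups$codes[[1]])
  plan$groups$kmers[[1]] <- c(km, plan$groups$kmers[[1]])
  enc <- encrypt_user_kmers(km, plan, pb)
  mr <- match_panel(enc, plan, pb)
  g1 <- he_decrypt(pb, mr$counts[[1]])[1]
  expect_equal(g1, 2)
})

test_that("step 4 aggregates the batch into slot 0", {
  pb <- plaintext_backend(32)
  expect_equal(he_decrypt(pb, step4_aggregate(pb, he_zero(pb), 8))[1], 0)
  d <- he_encrypt(pb, c(1, 0, 1, 1, rep(0, 28)))
  expect_equal(he_decrypt(pb, step4_aggregate(pb, d, 8))[1], 3)
  withr::with_seed(41, {
    v <- sample(0:3, 32, TRUE)
    dd <- he_encrypt(pb, v)
    expect_equal(he_decrypt(pb, step4_aggregate(pb, dd, 8))[1], sum(v[1:8]))
  })
})

test_that("match counts equal a naive string-matching scan and respect the truth", {
  cfg <- sim_config(n_residues = 4, flank_len = 25, read_len = 36, paired = FALSE,
                    depth = 3, substitution_prob = 0.5, seed = 51)
  sdp <- simulate_designed_panel(cfg, pdt = 0, k_cap = 20)
  reads <- simulate_reads(sdp$panel, sdp$sim$truth, sdp$config)
  uk <- kmerize_reads(reads, sdp$design$k, include_reverse_complement = FALSE)
  plan <- protocol_plan(sdp$design, l = 2, n_batch = 8)
  pb <- plaintext_backend(plan$spec$slots)
  enc <- encrypt_user_kmers(uk, plan, pb, dedupe = TRUE)
  mr <- match_panel(enc, plan, pb)
  got <- vapply(mr$counts, function(ct) he_decrypt(pb, ct)[1], numeric(1))
  expect_equal(got, oracle_match_counts(unique(uk$kmer), plan))
  rep <- decrypt_report(pb, mr)
  truth <- sdp$sim$truth
  expect_equal(rep$call[match(truth$id, rep$residue_id)], truth$planted_allele)
})

test_that("call rules: both alleles -> het, neither -> no-coverage flag", {
  pb <- plaintext_backend(16)
  mk_ct <- function(x) he_encrypt(pb, c(x, rep(0, 15)))
  res <- structure(list(
    groups = tibble::tibble(residue_id = rep(c("rA", "rB"), each = 2),
                            allele = rep(c("ref", "alt"), 2)),
    counts = list(mk_ct(5), mk_ct(5), mk_ct(0), mk_ct(0)),
    n_user_kmers = 10L, spec = block_spec(4, 2, 4)
  ), class = "match_result")
  rep <- decrypt_report(pb, res)
  expect_equal(rep$call[rep$residue_id == "rA"], "het")
  expect_equal(rep$call[rep$residue_id == "rB"], "no_coverage")
})

test_that("a single deviation at distance d leaves min(d, window limit) matching k-mers", {
  cfg <- sim_config(n_residues = 1, flank_len = 40, read_len = 60, paired = FALSE,
                    depth = 0, substitution_prob = 0, seed = 61)
  sdp <- simulate_designed_panel(cfg, pdt = 0, k_cap = 20)
  k <- sdp$design$k
  ent <- sdp$panel$entities[1, ]
  off <- sdp$panel$residues$offset[1]
  # one synthetic read centred on the residue with >= K flank on both sides
  start <- off - 30L
  read <- tibble::tibble(read_id = "r/1", mate = 1L,
                         seq = substr(ent$sequence, start + 1, start + 60),
                         entity_id = ent$entity_id, start = start, strand = "+")
  plan <- protocol_plan(sdp$design, l = 2, n_batch = 8)
  pb <- plaintext_backend(plan$spec$slots)
  for (d in c(1L, 3L, k - 1L, k + 5L)) {
    mut <- inject_deviations(read, sdp$panel, exact_distance = d, seed = d)
    uk <- kmerize_reads(mut, k, include_reverse_complement = FALSE)
    enc <- encrypt_user_kmers(uk, plan, pb, dedupe = FALSE)
    mr <- match_panel(enc, plan, pb)
    got <- vapply(mr$counts, function(ct) he_decrypt(pb, ct)[1], numeric(1))
    expect_equal(got, oracle_match_counts(uk$kmer, plan), info = paste("d =", d))
    ref_ct <- got[plan$groups$allele == "ref"]
    expect_equal(ref_ct, min(d, k), info = paste("d =", d))
  }
})

test_that("the protocol under RLWE equals the plaintext backend on a small panel", {
  md <- mini_design(seed = 71, n = 2, flank = 15)
  plan <- protocol_plan(md$design, l = 3, n_batch = 4)
  user <- c(plan$groups$kmers[[1]][1], plan$groups$kmers[[4]][2],
            strrep("A", md$design$k))
  pb <- plaintext_backend(max(plan$spec$slots, 256))
  pp <- rlwe_params(n_ring = max(2L * plan$spec$slots, 512L),
                    depth = ceiling(log2(plan$spec$b)))
  keys <- rlwe_keygen(pp, seed = 72, evk_powers = 2:plan$spec$b)
  rb <- rlwe_backend(pp, keys)
  rb <- he_prepare_rotations(rb, plan$rot_amounts, seed = 73)
  count_with <- function(backend) {
    enc <- encrypt_user_kmers(user, plan, backend)
    vapply(match_panel(enc, plan, backend)$counts,
           function(ct) he_decrypt(backend, ct)[1], numeric(1))
  }
  expect_equal(count_with(rb), count_with(pb))
  expect_equal(count_with(pb), oracle_match_counts(user, plan))
})
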