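toy_params <- function() rlwe_params(n_ring = 256, depth = 1)

test_that("ring parameters satisfy the batching congruences", {
  pp <- toy_params()
  expect_equal((pp$p - 1) %% (2 * pp$n_ring), 0)
  expect_true(all((pp$qs - 1) %% (2 * pp$n_ring) == 0))
  expect_equal(anyDuplicated(pp$qs), 0)
  expect_false(pp$p %in% pp$qs)
  expect_equal(pp$slots, pp$n_ring / 2)
})

test_that("key generation is seed-reproducible and satisfies the public-key relation", {
  pp <- toy_params()
  k1 <- rlwe_keygen(pp, seed = 3)
  k2 <- rlwe_keygen(pp, seed = 3)
  k3 <- rlwe_keygen(pp, seed = 4)
  expect_identical(k1$sk$s_coeff, k2$sk$s_coeff)
  expect_false(identical(k1$sk$s_coeff, k3$sk$s_coeff))
  # b + a*s = p*e: the payload reduces to 0 mod p and is tiny next to q
  payload <- kmerlock:::rns_add(pp, k1$pk$b, kmerlock:::rns_mul(pp, k1$pk$a, k1$sk$s_eval))
  coef <- kmerlock:::.eng_ntt(payload, pp$qs, pp$psis, TRUE)
  red <- kmerlock:::.eng_crt_mod_p(coef, pp$qs, pp$p)
  expect_true(all(red$values == 0))
  expect_lt(red$max_frac, 1e-10)
})

test_that("encryption round-trips, is randomized, and handles edge vectors", {
  pp <- toy_params()
  keys <- rlwe_keygen(pp, seed = 5)
  withr::with_seed(1, {
    m <- sample(0:(pp$p - 1), pp$slots, TRUE)
    ct <- rlwe_encrypt(keys, m)
    expect_equal(as.integer(rlwe_decrypt(keys, ct)), as.integer(m))
    ct2 <- rlwe_encrypt(keys, m)
    expect_false(identical(ct$comps[[1]], ct2$comps[[1]]))
    z <- rlwe_encrypt(keys, integer(pp$slots))
    expect_true(all(rlwe_decrypt(keys, z) == 0))
  })
  expect_error(rlwe_encrypt(keys, rep(pp$p, pp$slots)), "\\[0, p\\)")
})

test_that("homomorphic add, mult and rotate agree with the plaintext backend", {
  pp <- toy_params()
  keys <- rlwe_keygen(pp, seed = 6)
  keys <- rlwe_add_rot_keys(keys, 1:10, seed = 7)
  rb <- rlwe_backend(pp, keys)
  pb <- plaintext_backend(pp$slots, pp$p)
  withr::with_seed(8, {
    for (i in 1:30) {
      m1 <- sample(0:100, pp$slots, TRUE)
      m2 <- sample(0:100, pp$slots, TRUE)
      op <- sample(c("add", "mult", "rotate"), 1)
      c1 <- he_encrypt(rb, m1); p1 <- he_encrypt(pb, m1)
      if (op == "rotate") {
        r <- sample(1:10, 1)
        expect_equal(as.integer(he_decrypt(rb, he_rotate(rb, c1, r))),
                     as.integer(he_decrypt(pb, he_rotate(pb, p1, r))))
      } else {
        c2 <- he_encrypt(rb, m2); p2 <- he_encrypt(pb, m2)
        f <- if (op == "add") he_add else he_mult
        expect_equal(as.integer(he_decrypt(rb, f(rb, c1, c2))),
                     as.integer(he_decrypt(pb, f(pb, p1, p2))))
      }
    }
  })
})

test_that("rotation is cyclic: r = 0 is the identity and r + (slots - r) closes", {
  pp <- toy_params()
  keys <- rlwe_keygen(pp, seed = 9)
  keys <- rlwe_add_rot_keys(keys, c(5, pp$slots - 5), seed = 10)
  rb <- rlwe_backend(pp, keys)
  m <- withr::with_seed(3, sample(0:50, pp$slots, TRUE))
  ct <- he_encrypt(rb, m)
  expect_identical(he_rotate(rb, ct, 0), ct)
  back <- he_rotate(rb, he_rotate(rb, ct, 5), pp$slots - 5)
  expect_equal(as.integer(he_decrypt(rb, back)), as.integer(m))
  expect_error(he_rotate(rb, ct, 7), "rotation key for amount 7")
})

test_that("extended products relinearize correctly through higher key powers", {
  pp <- rlwe_params(n_ring = 256, depth = 2)
  keys <- rlwe_keygen(pp, seed = 11, evk_powers = 2:3)
  rb <- rlwe_backend(pp, keys)
  withr::with_seed(12, {
    ms <- replicate(3, sample(0:7, pp$slots, TRUE), simplify = FALSE)
    cts <- lapply(ms, he_encrypt, backend = rb)
    lazy <- he_mult_lazy(rb, he_mult_lazy(rb, cts[[1]], cts[[2]]), cts[[3]])
    expect_equal(length(lazy$comps), 4)
    rel <- he_relin(rb, lazy)
    expect_equal(length(rel$comps), 2)
    want <- as.integer((ms[[1]] * ms[[2]] * ms[[3]]) %% pp$p)
    expect_equal(as.integer(he_decrypt(rb, rel)), want)
    expect_equal(as.integer(rlwe_decrypt(keys, lazy)), want)  # dec handles extended cts
  })
})

test_that("noise budget shrinks monotonically and decryption fails loudly when spent", {
  pp <- toy_params()
  keys <- rlwe_keygen(pp, seed = 13)
  rb <- rlwe_backend(pp, keys)
  m <- rep(1L, pp$slots)
  ct <- he_encrypt(rb, m)
  b0 <- he_noise_budget(rb, ct)
  ca <- he_add(rb, ct, ct)
  cm <- he_mult(rb, ct, ct)
  expect_lte(he_noise_budget(rb, ca), b0)
  expect_lt(he_noise_budget(rb, cm), b0)
  # the depth-1 preset refuses a multiplication chain it cannot support,
  # before results can corrupt silently
  cm2 <- he_mult(rb, cm, cm)
  expect_error(he_mult(rb, cm2, cm2), "budget")
  # observed payload magnitude stays at or below the tracked estimate
  # (the long-double CRT gauge cannot resolve payloads below ~ q / 2^59)
  obs <- attr(rlwe_decrypt(keys, cm), "observed_log2_payload")
  expect_lt(obs, max(cm$noise, pp$log2q - 59) + 1)
})

test_that("slot packing is a ring isomorphism onto slotwise arithmetic", {
  pp <- toy_params()
  withr::with_seed(14, {
    m1 <- sample(0:(pp$p - 1), pp$slots, TRUE)
    m2 <- sample(0:(pp$p - 1), pp$slots, TRUE)
    c1 <- kmerlock:::encode_slots(pp, m1)
    c2 <- kmerlock:::encode_slots(pp, m2)
    expect_equal(as.integer(kmerlock:::decode_slots(pp, c1)), as.integer(m1))
    # negacyclic polynomial product of the encodings = slotwise product
    e1 <- kmerlock:::.eng_ntt(matrix(c1, nrow = 1), pp$p, pp$psi_p, FALSE)
    e2 <- kmerlock:::.eng_ntt(matrix(c2, nrow = 1), pp$p, pp$psi_p, FALSE)
    prod_poly <- kmerlock:::.eng_ntt(kmerlock:::.eng_pw(e1, e2, pp$p, 2L), pp$p, pp$psi_p, TRUE)
    expect_equal(as.integer(kmerlock:::decode_slots(pp, prod_poly[1, ])),
                 as.integer((m1 * m2) %% pp$p))
  })
})

test_that("mismatched key material is rejected by fingerprint", {
  pp1 <- toy_params()
  pp2 <- rlwe_params(n_ring = 512, depth = 1)
  k1 <- rlwe_keygen(pp1, seed = 1)
  k2 <- rlwe_keygen(pp2, seed = 1)
  expect_error(rlwe_backend(pp1, k2), "fingerprint")
  rb <- rlwe_backend(pp2, k2)
  ct <- he_encrypt(rb, 1:5)
  expect_error(rlwe_decrypt(k1, ct), "fingerprint")
})
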