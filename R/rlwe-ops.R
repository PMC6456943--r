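new_rlwe_ct <- function(params, comps, noise) {
  structure(list(comps = comps, noise = noise,
                 fingerprint = params$fingerprint),
            class = "rlwe_ct")
}

#' @export
print.rlwe_ct <- function(x, ...) {
  cat(sprintf("<rlwe_ct> %d components; noise budget ~ %.0f bits\n",
              length(x$comps), attr(x, "budget") %||% NA))
  invisible(x)
}

check_fingerprint <- function(params, ct) {
  if (!identical(params$fingerprint, ct$fingerprint)) {
    abort("ciphertext was produced under different ring parameters (fingerprint mismatch)")
  }
}

noise_budget <- function(params, ct) params$log2q - 1 - ct$noise

check_budget <- function(params, noise) {
  if (noise > params$log2q - 1) {
    abort(sprintf(
      "noise budget exhausted (estimated %.0f of %.0f bits): deepen the parameter preset before results corrupt silently",
      noise, params$log2q - 1))
  }
  noise
}

#' Encrypt a slot vector under an RLWE public key
#'
#' The message vector (values in `[0, p)`) is packed into plaintext slots and
#' encrypted as `(m + v*b + p*e0, v*a + p*e1)` with small `v`, `e0`, `e1`.
#'
#' @param keys `rlwe_keys` (only the public part is used).
#' @param m Integer vector of length at most the slot capacity.
#' @return An `rlwe_ct`.
#' @export
rlwe_encrypt <- function(keys, m) {
  params <- keys$params
  if (any(m >= params$p) || any(m < 0)) abort("slot values must lie in [0, p)")
  mc <- encode_slots(params, m)
  mc[mc > params$p / 2] <- mc[mc > params$p / 2] - params$p   # centre
  v <- sample_small(params$n_ring, params$sigma, "ternary")
  e0 <- sample_small(params$n_ring, params$sigma)
  e1 <- sample_small(params$n_ring, params$sigma)
  v_eval <- rns_ntt(params, v)
  c0 <- rns_add(params, rns_ntt(params, mc + params$p * e0),
                rns_mul(params, v_eval, keys$pk$b))
  c1 <- rns_add(params, rns_mul(params, v_eval, keys$pk$a),
                rns_ntt(params, params$p * e1))
  new_rlwe_ct(params, list(c0, c1), params$noise$fresh)
}

#' Decrypt an RLWE ciphertext to its slot vector
#'
#' Computes `sum_i c_i * s^i`, reduces the centered lift modulo `p`, and
#' unpacks the slots. Fails loudly if the observed payload magnitude shows
#' the noise has (nearly) consumed the modulus.
#'
#' @param keys `rlwe_keys` (secret part required).
#' @param ct An `rlwe_ct` (possibly extended / unrelinearized).
#' @return Integer vector of slot values in `[0, p)`.
#' @export
rlwe_decrypt <- function(keys, ct) {
  params <- keys$params
  check_fingerprint(params, ct)
  payload <- ct$comps[[1]]
  s_pow <- NULL
  for (i in seq_along(ct$comps)[-1]) {
    s_pow <- if (is.null(s_pow)) keys$sk$s_eval else rns_mul(params, s_pow, keys$sk$s_eval)
    payload <- rns_add(params, payload, rns_mul(params, ct$comps[[i]], s_pow))
  }
  coef <- .eng_ntt(payload, params$qs, params$psis, TRUE)
  res <- .eng_crt_mod_p(coef, params$qs, params$p)
  if (res$max_frac > 0.45) {
    abort("decryption integrity failure: payload fills the ciphertext modulus (noise budget exhausted)")
  }
  out <- decode_slots(params, res$values)
  attr(out, "observed_log2_payload") <- log2(max(res$max_frac, 2^-60)) + params$log2q
  out
}

rlwe_add_ct <- function(params, c1, c2) {
  check_fingerprint(params, c1); check_fingerprint(params, c2)
  n1 <- length(c1$comps); n2 <- length(c2$comps)
  comps <- vector("list", max(n1, n2))
  for (i in seq_len(max(n1, n2))) {
    a <- if (i <= n1) c1$comps[[i]] else NULL
    b <- if (i <= n2) c2$comps[[i]] else NULL
    comps[[i]] <- if (is.null(a)) b else if (is.null(b)) a else rns_add(params, a, b)
  }
  new_rlwe_ct(params, comps, check_budget(params, log2add(c1$noise, c2$noise)))
}

# Tensor product without relinearization: component lists convolve, so the
# result decrypts under (1, s, s^2, ...). Noise multiplies.
rlwe_mult_lazy <- function(params, c1, c2) {
  check_fingerprint(params, c1); check_fingerprint(params, c2)
  n1 <- length(c1$comps); n2 <- length(c2$comps)
  comps <- rep(list(NULL), n1 + n2 - 1L)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    pr <- rns_mul(params, c1$comps[[i]], c2$comps[[j]])
    k <- i + j - 1L
    comps[[k]] <- if (is.null(comps[[k]])) pr else rns_add(params, comps[[k]], pr)
  }
  noise <- check_budget(params, c1$noise + c2$noise + params$noise$mult_extra)
  new_rlwe_ct(params, comps, noise)
}

# Key-switch every component beyond (c0, c1) back onto s.
rlwe_relinearize <- function(params, ct, keys) {
  if (length(ct$comps) <= 2L) return(ct)
  c0 <- ct$comps[[1]]
  c1 <- if (length(ct$comps) >= 2) ct$comps[[2]] else zero_mat(params)
  noise <- ct$noise
  for (i in seq_along(ct$comps)) {
    if (i <= 2) next
    key <- keys$evk[[as.character(i - 1L)]]
    if (is.null(key)) abort(sprintf("no relinearization key for secret power %d", i - 1L))
    kk <- .eng_keyswitch(ct$comps[[i]], key$b, key$a, params$qs, params$psis)
    c0 <- rns_add(params, c0, kk$b)
    c1 <- rns_add(params, c1, kk$a)
    noise <- log2add(noise, params$noise$ks)
  }
  new_rlwe_ct(params, list(c0, c1), check_budget(params, noise))
}

rlwe_mult_ct <- function(params, c1, c2, keys) {
  rlwe_relinearize(params, rlwe_mult_lazy(params, c1, c2), keys)
}

rlwe_rotate_ct <- function(params, ct, r, keys) {
  check_fingerprint(params, ct)
  r <- as.integer(r) %% params$slots
  if (r == 0L) return(ct)
  if (length(ct$comps) != 2L) abort("rotate expects a relinearized (2-component) ciphertext")
  key <- keys$rot_keys[[as.character(r)]]
  if (is.null(key)) abort(sprintf("no rotation key for amount %d", r))
  perm <- galois_perm(params, r)
  b_rot <- ct$comps[[1]][, perm, drop = FALSE]
  a_rot <- ct$comps[[2]][, perm, drop = FALSE]
  kk <- .eng_keyswitch(a_rot, key$b, key$a, params$qs, params$psis)
  new_rlwe_ct(params, list(rns_add(params, b_rot, kk$b), kk$a),
              check_budget(params, log2add(ct$noise, params$noise$ks)))
}
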