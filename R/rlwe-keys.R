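sample_small <- function(n, sigma, type = c("gaussian", "ternary")) {
  type <- match.arg(type)
  if (type == "ternary") sample(c(-1, 0, 1), n, replace = TRUE)
  else round(rnorm(n, 0, sigma))
}

# RNS residue matrix (n_primes x n) of an integer coefficient vector.
rns_mat <- function(params, coeffs) {
  k <- length(params$qs)
  out <- matrix(0, nrow = k, ncol = params$n_ring)
  for (i in seq_len(k)) out[i, ] <- coeffs %% params$qs[i]
  out
}

rns_ntt <- function(params, coeffs) {
  .eng_ntt(rns_mat(params, coeffs), params$qs, params$psis, FALSE)
}

uniform_eval <- function(params) {
  k <- length(params$qs)
  t(vapply(params$qs, function(q) floor(runif(params$n_ring) * q), numeric(params$n_ring)))
}

rns_add <- function(params, a, b) .eng_pw(a, b, params$qs, 0L)
rns_sub <- function(params, a, b) .eng_pw(a, b, params$qs, 1L)
rns_mul <- function(params, a, b) .eng_pw(a, b, params$qs, 2L)

zero_mat <- function(params) matrix(0, nrow = length(params$qs), ncol = params$n_ring)

# One key-switching key: an encryption of `target` (a ring element in eval
# form, typically s^2 or s(X^g)) under s, split into per-prime CRT digits.
make_ks_key <- function(params, s_eval, target_eval) {
  k <- length(params$qs)
  ksb <- vector("list", k); ksa <- vector("list", k)
  for (j in seq_len(k)) {
    a_j <- uniform_eval(params)
    e_j <- sample_small(params$n_ring, params$sigma)
    b_j <- rns_sub(params, rns_ntt(params, params$p * e_j), rns_mul(params, a_j, s_eval))
    iota_t <- zero_mat(params)
    iota_t[j, ] <- target_eval[j, ]
    b_j <- rns_add(params, b_j, iota_t)
    ksb[[j]] <- b_j; ksa[[j]] <- a_j
  }
  list(b = ksb, a = ksa)
}

#' Generate an RLWE key set
#'
#' Secret key `s` sampled from the error distribution (ternary by default),
#' public key `(b, a)` with `b = -a*s + p*e`, relinearization keys for the
#' requested secret-key powers, and (optionally later) rotation keys.
#'
#' @param params [rlwe_params()].
#' @param seed Integer seed for reproducible keys.
#' @param evk_powers Secret-key powers to build relinearization keys for
#'   (default `2`; extended ciphertexts from lazy products need higher powers).
#' @param secret `"ternary"` or `"gaussian"` secret distribution.
#' @return Object of class `rlwe_keys` with `sk`, `pk`, `evk`, empty
#'   `rot_keys`, and the params fingerprint.
#' @export
rlwe_keygen <- function(params, seed = NULL, evk_powers = 2, secret = "ternary") {
  with_seed(seed, {
    s_coeff <- sample_small(params$n_ring, params$sigma, type = secret)
    s_eval <- rns_ntt(params, s_coeff)
    a <- uniform_eval(params)
    e <- sample_small(params$n_ring, params$sigma)
    b <- rns_sub(params, rns_ntt(params, params$p * e), rns_mul(params, a, s_eval))
    evk <- list()
    s_pow <- s_eval
    max_pow <- max(2, evk_powers)
    for (pw in 2:max_pow) {
      s_pow <- rns_mul(params, s_pow, s_eval)
      if (pw %in% evk_powers || pw == 2) {
        evk[[as.character(pw)]] <- make_ks_key(params, s_eval, s_pow)
      }
    }
    structure(list(sk = list(s_coeff = s_coeff, s_eval = s_eval),
                   pk = list(b = b, a = a), evk = evk,
                   rot_keys = list(), params = params,
                   fingerprint = params$fingerprint),
              class = "rlwe_keys")
  })
}

#' Add rotation keys for specific rotation amounts
#'
#' Slot rotation by `r` is the ring automorphism `X -> X^(5^r)` followed by a
#' key switch back to `s`; each amount needs its own switching key, and a
#' rotation without its key is an error naming the amount.
#'
#' @param keys `rlwe_keys` from [rlwe_keygen()].
#' @param amounts Integer rotation amounts (mod slot count).
#' @param seed Optional seed.
#' @return The key set with `rot_keys` extended.
#' @export
rlwe_add_rot_keys <- function(keys, amounts, seed = NULL) {
  params <- keys$params
  amounts <- unique(as.integer(amounts) %% params$slots)
  amounts <- setdiff(amounts, c(0L, as.integer(names(keys$rot_keys))))
  with_seed(seed, {
    for (r in amounts) {
      perm <- galois_perm(params, r)
      s_rot <- keys$sk$s_eval[, perm, drop = FALSE]
      keys$rot_keys[[as.character(r)]] <- make_ks_key(params, keys$sk$s_eval, s_rot)
    }
  })
  keys
}

#' @export
print.rlwe_keys <- function(x, ...) {
  cat(sprintf("<rlwe_keys> ring n = %d; evk powers: %s; rotation keys: %d\n",
              x$params$n_ring, paste(names(x$evk), collapse = ","),
              length(x$rot_keys)))
  invisible(x)
}
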