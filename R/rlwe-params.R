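log2add <- function(a, b) {
  m <- pmax(a, b)
  m + log2(1 + 2^(-abs(a - b)))
}

small_prime_1mod <- function(m, at_least = 2) {
  k <- max(1, ceiling((at_least - 1) / m))
  repeat {
    cand <- m * k + 1
    if (cand > 2 && all(cand %% 2:floor(sqrt(cand)) != 0)) return(cand)
    k <- k + 1
  }
}

# Heuristic (central-limit style) noise model in log2 units. `floor_ks` is the
# additive key-switch noise with single-prime digits; a product tree of depth d
# roughly squares the payload bound per level with a sqrt(n) convolution factor.
noise_model <- function(n_ring, p, sigma, n_primes) {
  list(
    fresh = log2(p) + log2(8 * sigma^2 * sqrt(n_ring) + 2 * sigma + 1),
    ks = log2(p) + log2(8 * sigma) + 30 + 0.5 * log2(n_ring * n_primes),
    mult_extra = 0.5 * log2(n_ring) + 2
  )
}

primes_for_depth <- function(n_ring, p, sigma, depth, headroom = 20) {
  for (k in 2:40) {
    nm <- noise_model(n_ring, p, sigma, k)
    t <- log2add(nm$fresh, nm$ks)
    for (d in seq_len(depth)) t <- 2 * t + nm$mult_extra
    t <- t + 14   # aggregation slack: sums over panel k-mers, batches, slot rotations
    if (t + headroom <= 30 * k - 1) return(k)
  }
  abort("no RNS prime count supports this depth at 30-bit primes")
}

#' Ring parameters for the RLWE backend
#'
#' A power-of-two cyclotomic ring `Z_q[X]/(X^n + 1)` with an RNS ciphertext
#' modulus (a product of 30-bit NTT primes) and a prime plaintext modulus
#' `p = 1 (mod 2n)` so the plaintext ring splits into `n` evaluation slots;
#' the usable packing dimension is `n/2` (one orbit of the slot-rotation
#' group). These parameter sets are sized for desk-scale experiments and are
#' NOT production-secure.
#'
#' @param n_ring Ring degree, a power of two (default 2048).
#' @param depth Multiplicative depth the preset must support; decides the
#'   number of ciphertext primes.
#' @param p Plaintext modulus; default is the smallest prime `= 1 (mod 2n)`
#'   at least `p_min`. Must exceed any count the protocol can produce.
#' @param p_min Lower bound for the default plaintext modulus.
#' @param sigma Error distribution width (discrete Gaussian, default 3.2).
#' @param n_primes Override the automatic ciphertext prime count.
#' @return Object of class `rlwe_params`.
#' @export
rlwe_params <- function(n_ring = 2048, depth = 2, p = NULL, p_min = 4096,
                        sigma = 3.2, n_primes = NULL) {
  if (!is_power_of_two(n_ring) || n_ring < 16) abort("n_ring must be a power of two >= 16")
  m_ring <- 2L * as.integer(n_ring)
  if (is.null(p)) p <- small_prime_1mod(m_ring, at_least = p_min)
  if ((p - 1) %% m_ring != 0) abort("p must be = 1 (mod 2*n_ring) for slot batching")
  if (is.null(n_primes)) n_primes <- primes_for_depth(n_ring, p, sigma, depth)
  qs <- .eng_find_primes(m_ring, as.integer(n_primes), avoid = p)
  psis <- vapply(qs, function(q) .eng_primitive_root(q, n_ring), numeric(1))
  psi_p <- .eng_primitive_root(p, n_ring)

  nslots <- n_ring / 2L
  # slot t lives at the evaluation point psi^(5^t); orbit of the Galois
  # element 5 (and its mirror orbit) covers all odd exponents mod 2n.
  e1 <- numeric(nslots); e <- 1
  for (t in seq_len(nslots)) { e1[t] <- e; e <- (e * 5) %% m_ring }
  pos1 <- (e1 + 1) / 2          # 1-based NTT output position of exponent e
  pos2 <- (m_ring - e1 + 1) / 2

  structure(list(
    n_ring = as.integer(n_ring), m_ring = m_ring, p = p, sigma = sigma,
    qs = qs, psis = psis, psi_p = psi_p,
    log2q = sum(log2(qs)), depth = depth,
    slots = as.integer(nslots), pos1 = as.integer(pos1), pos2 = as.integer(pos2),
    noise = noise_model(n_ring, p, sigma, length(qs)),
    fingerprint = paste0("n", n_ring, "p", p, "q", paste(qs %% 997, collapse = "."))
  ), class = "rlwe_params")
}

#' @export
print.rlwe_params <- function(x, ...) {
  cat(sprintf(
    "<rlwe_params> n = %d, %d slots, p = %d, q = product of %d 30-bit primes (log2 q = %.0f), sigma = %.1f\n  toy parameters for testing; not production-secure\n",
    x$n_ring, x$slots, x$p, length(x$qs), x$log2q, x$sigma))
  invisible(x)
}

# Galois permutation of eval-domain columns for rotation by r slots:
# new value at exponent e is the old value at exponent e * 5^r.
galois_perm <- function(params, r) {
  g <- 1
  r <- r %% params$slots
  for (i in seq_len(r)) g <- (g * 5) %% params$m_ring
  j <- seq_len(params$n_ring)
  e <- 2 * j - 1
  e2 <- (e * g) %% params$m_ring
  as.integer((e2 + 1) / 2)
}

encode_slots <- function(params, m) {
  m <- as.numeric(m) %% params$p
  if (length(m) > params$slots) abort("message longer than slot capacity")
  m <- c(m, numeric(params$slots - length(m)))
  ev <- numeric(params$n_ring)
  ev[params$pos1] <- m
  ev[params$pos2] <- m
  .eng_ntt(matrix(ev, nrow = 1), params$p, params$psi_p, TRUE)[1, ]
}

decode_slots <- function(params, poly_mod_p) {
  ev <- .eng_ntt(matrix(poly_mod_p, nrow = 1), params$p, params$psi_p, FALSE)[1, ]
  ev[params$pos1]
}
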