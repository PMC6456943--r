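#' Homomorphic vector backends
#'
#' The equality-test protocol runs against a backend exposing encrypt,
#' decrypt, slotwise add/multiply and cyclic slot rotation. Two backends
#' share this contract: the RLWE backend computes on real ciphertexts; the
#' plaintext backend performs the identical arithmetic on clear integer
#' vectors mod `p` and serves as the correctness oracle and fast mode.
#'
#' @param params [rlwe_params()] for the RLWE backend.
#' @param keys [rlwe_keygen()] key set.
#' @param slots Slot count for the plaintext backend.
#' @param p Plaintext modulus for the plaintext backend.
#' @return A backend object (class `he_backend`).
#' @name backends
NULL

#' @rdname backends
#' @export
rlwe_backend <- function(params, keys) {
  stopifnot(inherits(params, "rlwe_params"), inherits(keys, "rlwe_keys"))
  if (!identical(params$fingerprint, keys$fingerprint)) {
    abort("keys were generated under different parameters (fingerprint mismatch)")
  }
  structure(list(params = params, keys = keys),
            class = c("rlwe_backend", "he_backend"))
}

#' @rdname backends
#' @export
plaintext_backend <- function(slots, p = 12289L) {
  stopifnot(is_power_of_two(slots))
  structure(list(slots = as.integer(slots), p = as.integer(p)),
            class = c("plaintext_backend", "he_backend"))
}

#' @export
print.rlwe_backend <- function(x, ...) {
  cat("<rlwe_backend>\n"); print(x$params); invisible(x)
}
#' @export
print.plaintext_backend <- function(x, ...) {
  cat(sprintf("<plaintext_backend> %d slots mod %d (exact reference arithmetic)\n",
              x$slots, x$p)); invisible(x)
}

#' @export
he_slots <- function(backend) UseMethod("he_slots")
#' @export
he_slots.rlwe_backend <- function(backend) backend$params$slots
#' @export
he_slots.plaintext_backend <- function(backend) backend$slots

#' @export
he_ptmod <- function(backend) UseMethod("he_ptmod")
#' @export
he_ptmod.rlwe_backend <- function(backend) backend$params$p
#' @export
he_ptmod.plaintext_backend <- function(backend) backend$p

#' Backend operations
#'
#' Generic encrypt/decrypt/add/multiply/rotate dispatched on the backend.
#' `he_mult_lazy()` multiplies without relinearizing (extended ciphertext);
#' `he_relin()` switches an extended ciphertext back to two components;
#' `he_prepare_rotations()` generates any key material rotations need.
#'
#' @param backend An `he_backend`.
#' @param m Slot vector; `ct`, `c1`, `c2` ciphertexts; `r` rotation amount;
#'   `amounts` rotation amounts; `seed` RNG seed.
#' @name he-ops
NULL

#' @rdname he-ops
#' @export
he_encrypt <- function(backend, m) UseMethod("he_encrypt")
#' @rdname he-ops
#' @export
he_decrypt <- function(backend, ct) UseMethod("he_decrypt")
#' @rdname he-ops
#' @export
he_add <- function(backend, c1, c2) UseMethod("he_add")
#' @rdname he-ops
#' @export
he_mult <- function(backend, c1, c2) UseMethod("he_mult")
#' @rdname he-ops
#' @export
he_mult_lazy <- function(backend, c1, c2) UseMethod("he_mult_lazy")
#' @rdname he-ops
#' @export
he_relin <- function(backend, ct) UseMethod("he_relin")
#' @rdname he-ops
#' @export
he_rotate <- function(backend, ct, r) UseMethod("he_rotate")
#' @rdname he-ops
#' @export
he_prepare_rotations <- function(backend, amounts, seed = NULL) {
  UseMethod("he_prepare_rotations")
}

#' @export
he_encrypt.rlwe_backend <- function(backend, m) rlwe_encrypt(backend$keys, m)
#' @export
he_decrypt.rlwe_backend <- function(backend, ct) rlwe_decrypt(backend$keys, ct)
#' @export
he_add.rlwe_backend <- function(backend, c1, c2) rlwe_add_ct(backend$params, c1, c2)
#' @export
he_mult.rlwe_backend <- function(backend, c1, c2) rlwe_mult_ct(backend$params, c1, c2, backend$keys)
#' @export
he_mult_lazy.rlwe_backend <- function(backend, c1, c2) rlwe_mult_lazy(backend$params, c1, c2)
#' @export
he_relin.rlwe_backend <- function(backend, ct) rlwe_relinearize(backend$params, ct, backend$keys)
#' @export
he_rotate.rlwe_backend <- function(backend, ct, r) rlwe_rotate_ct(backend$params, ct, r, backend$keys)
#' @export
he_prepare_rotations.rlwe_backend <- function(backend, amounts, seed = NULL) {
  backend$keys <- rlwe_add_rot_keys(backend$keys, amounts, seed = seed)
  backend
}

new_plx_ct <- function(v, p) structure(list(v = as.integer(v %% p), p = p), class = "plx_ct")

#' @export
he_encrypt.plaintext_backend <- function(backend, m) {
  if (length(m) > backend$slots) abort("message longer than slot capacity")
  if (any(m >= backend$p) || any(m < 0)) abort("slot values must lie in [0, p)")
  new_plx_ct(c(m, integer(backend$slots - length(m))), backend$p)
}
#' @export
he_decrypt.plaintext_backend <- function(backend, ct) ct$v
#' @export
he_add.plaintext_backend <- function(backend, c1, c2) {
  new_plx_ct((c1$v + c2$v) %% backend$p, backend$p)
}
#' @export
he_mult.plaintext_backend <- function(backend, c1, c2) {
  new_plx_ct((as.numeric(c1$v) * as.numeric(c2$v)) %% backend$p, backend$p)
}
#' @export
he_mult_lazy.plaintext_backend <- he_mult.plaintext_backend
#' @export
he_relin.plaintext_backend <- function(backend, ct) ct
#' @export
he_rotate.plaintext_backend <- function(backend, ct, r) {
  s <- backend$slots
  r <- ((as.integer(r) %% s) + s) %% s
  if (r == 0L) return(ct)
  idx <- ((seq_len(s) - 1L + r) %% s) + 1L
  new_plx_ct(ct$v[idx], backend$p)
}
#' @export
he_prepare_rotations.plaintext_backend <- function(backend, amounts, seed = NULL) backend

#' Remaining noise budget of a ciphertext, in bits
#'
#' @param backend An `he_backend`.
#' @param ct A ciphertext of that backend.
#' @return Bits of headroom before decryption fails (Inf for the plaintext
#'   backend).
#' @export
he_noise_budget <- function(backend, ct) UseMethod("he_noise_budget")
#' @export
he_noise_budget.rlwe_backend <- function(backend, ct) noise_budget(backend$params, ct)
#' @export
he_noise_budget.plaintext_backend <- function(backend, ct) Inf
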