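# JSON envelopes for key material, ciphertext bundles and match results.
# Sized for the desk-scale parameter presets; every envelope carries the
# params fingerprint so mismatched material fails fast.

params_meta <- function(params) {
  list(n_ring = params$n_ring, p = params$p, sigma = params$sigma,
       depth = params$depth, qs = params$qs)
}

params_from_meta <- function(meta) {
  pp <- rlwe_params(n_ring = as.integer(meta$n_ring), depth = as.numeric(meta$depth),
                    p = as.numeric(meta$p), sigma = as.numeric(meta$sigma),
                    n_primes = length(meta$qs))
  if (!isTRUE(all.equal(pp$qs, as.numeric(unlist(meta$qs))))) {
    abort("stored ciphertext primes do not match this build's parameter derivation")
  }
  pp
}

# JSON is read without simplification, so a matrix arrives as a list of
# row lists.
mat_from_json <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && is.list(x[[1]])) return(do.call(rbind, lapply(x, as.numeric)))
  matrix(as.numeric(unlist(x)), nrow = 1)
}

ks_key_to_json <- function(key) list(b = key$b, a = key$a)
ks_key_from_json <- function(x) {
  list(b = lapply(x$b, mat_from_json), a = lapply(x$a, mat_from_json))
}

#' Write / read RLWE key material as a JSON envelope
#'
#' @param keys `rlwe_keys`.
#' @param path Output path.
#' @param private Include the secret key (patient side) or only the public
#'   evaluation material (hospital side).
#' @return The path (write) or an `rlwe_keys` object (read; `sk` is NULL in
#'   a public envelope).
#' @export
write_keys <- function(keys, path, private = TRUE) {
  env <- list(
    format = "kmerlock-keys-1", created = format(Sys.time(), tz = "UTC"),
    private = private, params = params_meta(keys$params),
    pk = keys$pk, evk = lapply(keys$evk, ks_key_to_json),
    rot_keys = lapply(keys$rot_keys, ks_key_to_json)
  )
  if (private) env$sk <- list(s_coeff = keys$sk$s_coeff)
  jsonlite::write_json(env, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_keys <- function(path) {
  env <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(env$format, "kmerlock-keys-1")) abort("not a kmerlock key envelope")
  params <- params_from_meta(env$params)
  sk <- NULL
  if (!is.null(env$sk)) {
    s_coeff <- as.numeric(unlist(env$sk$s_coeff))
    sk <- list(s_coeff = s_coeff, s_eval = rns_ntt(params, s_coeff))
  }
  structure(list(
    sk = sk,
    pk = list(b = mat_from_json(env$pk$b), a = mat_from_json(env$pk$a)),
    evk = lapply(env$evk, ks_key_from_json),
    rot_keys = lapply(env$rot_keys, ks_key_from_json),
    params = params, fingerprint = params$fingerprint
  ), class = "rlwe_keys")
}

ct_to_json <- function(ct) list(comps = ct$comps, noise = ct$noise)
ct_from_json <- function(x, params) {
  new_rlwe_ct(params, lapply(x$comps, mat_from_json), as.numeric(x$noise))
}

#' Write / read an encrypted user K-mer bundle
#'
#' @param enc `encrypted_kmers` from [encrypt_user_kmers()].
#' @param params The `rlwe_params` the ciphertexts live under.
#' @param path Output path.
#' @export
write_ciphertext_bundle <- function(enc, params, path) {
  env <- list(
    format = "kmerlock-ctxt-1", params = params_meta(params),
    spec = unclass(enc$spec), n_kmers = enc$n_kmers,
    batches = lapply(enc$batches, function(b) lapply(b, ct_to_json))
  )
  jsonlite::write_json(env, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ciphertext_bundle
#' @export
read_ciphertext_bundle <- function(path) {
  env <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(env$format, "kmerlock-ctxt-1")) abort("not a kmerlock ciphertext bundle")
  params <- params_from_meta(env$params)
  spec <- structure(lapply(env$spec, function(v) as.integer(v)), class = "block_spec")
  batches <- lapply(env$batches, function(b) lapply(b, ct_from_json, params = params))
  structure(list(batches = batches, spec = spec,
                 n_kmers = as.integer(env$n_kmers), params = params),
            class = "encrypted_kmers")
}

#' Write / read an encrypted match result
#'
#' @param result `match_result` from [match_panel()].
#' @param params The `rlwe_params`.
#' @param path Output path.
#' @export
write_match_result <- function(result, params, path) {
  env <- list(
    format = "kmerlock-result-1", params = params_meta(params),
    groups = result$groups, n_user_kmers = result$n_user_kmers,
    spec = unclass(result$spec),
    counts = lapply(result$counts, ct_to_json)
  )
  jsonlite::write_json(env, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_match_result
#' @export
read_match_result <- function(path) {
  env <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(env$format, "kmerlock-result-1")) abort("not a kmerlock match result")
  params <- params_from_meta(env$params)
  spec <- structure(lapply(env$spec, function(v) as.integer(v)), class = "block_spec")
  groups <- tibble(residue_id = vapply(env$groups, function(g) g$residue_id, character(1)),
                   allele = vapply(env$groups, function(g) g$allele, character(1)))
  structure(list(groups = groups,
                 counts = lapply(env$counts, ct_from_json, params = params),
                 n_user_kmers = as.integer(env$n_user_kmers), spec = spec,
                 params = params),
            class = "match_result")
}
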