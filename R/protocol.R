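#' Zero ciphertext of a backend
#'
#' @param backend An `he_backend`.
#' @return Ciphertext decrypting to the all-zero slot vector.
#' @export
he_zero <- function(backend) UseMethod("he_zero")
#' @export
he_zero.plaintext_backend <- function(backend) new_plx_ct(integer(backend$slots), backend$p)
#' @export
he_zero.rlwe_backend <- function(backend) {
  p <- backend$params
  new_rlwe_ct(p, list(zero_mat(p), zero_mat(p)), 0)
}

#' Plan the homomorphic equality test for a designed panel
#'
#' Fixes the block layout and pre-computes, for every (residue, allele)
#' group of SNP-covering panel K-mers, the quaternary block values whose
#' rotations the hospital will apply. Only these plaintext codes — never the
#' patient data — are visible to the hospital side.
#'
#' @param design A `kmer_design` (or `kmer_sets`) providing set A.
#' @param l Block size in bases.
#' @param n_batch User K-mers per ciphertext batch (N).
#' @param capacity Optional backend slot capacity for validation.
#' @return Object of class `protocol_plan` with the [block_spec()], the
#'   grouped panel codes, and the rotation amounts the protocol needs.
#' @export
protocol_plan <- function(design, l, n_batch, capacity = NULL) {
  ks <- if (inherits(design, "kmer_design")) design$kmer_sets else design
  spec <- block_spec(ks$k, l, n_batch, capacity)
  a <- ks$set_a
  groups <- a |>
    dplyr::group_by(.data$residue_id, .data$allele) |>
    dplyr::summarise(kmers = list(.data$seq), .groups = "drop")
  groups$codes <- purrr::map(groups$kmers, function(km) {
    bv <- block_values(km, spec)
    if (spec$b == 1L) bv <- matrix(bv, nrow = 1L)
    bv
  })
  values_present <- sort(unique(unlist(groups$codes)))
  rot <- unique(c(values_present * spec$n_batch,
                  seq_len(spec$n_batch - 1L)))
  rot <- rot[rot %% spec$slots != 0]
  if (any(values_present * spec$n_batch >= spec$slots)) {
    abort("internal: rotation amount reaches past the slot vector")
  }
  structure(list(spec = spec, groups = groups, rot_amounts = rot),
            class = "protocol_plan")
}

#' @export
print.protocol_plan <- function(x, ...) {
  cat(sprintf("<protocol_plan> %d (residue, allele) groups, %d panel k-mers; ",
              nrow(x$groups), sum(lengths(x$groups$kmers))))
  print(x$spec)
  invisible(x)
}

#' Encrypt user K-mers as batched indicator vectors
#'
#' Splits the user K-mer list into batches of `N`, builds the per-block
#' indicator vectors for each batch and encrypts them under the backend.
#'
#' @param kmers Character vector of user K-mers (or the tibble from
#'   [kmerize_reads()]).
#' @param plan A [protocol_plan()].
#' @param backend The patient-side backend used for encryption.
#' @param dedupe Drop duplicate K-mers before batching; counts then tally
#'   distinct matching K-mers (fewer batches, less to transmit).
#' @return Object of class `encrypted_kmers`: list of batches, each holding
#'   `b` ciphertexts, plus the total K-mer count.
#' @export
encrypt_user_kmers <- function(kmers, plan, backend, dedupe = FALSE) {
  if (is.data.frame(kmers)) kmers <- kmers$kmer
  if (dedupe) kmers <- unique(kmers)
  spec <- plan$spec
  if (spec$slots > he_slots(backend)) {
    abort(sprintf("plan needs %d slots but backend provides %d: reduce N or L",
                  spec$slots, he_slots(backend)))
  }
  nb <- max(1L, ceiling(length(kmers) / spec$n_batch))
  batches <- vector("list", nb)
  for (i in seq_len(nb)) {
    idx <- ((i - 1L) * spec$n_batch + 1L):min(i * spec$n_batch, length(kmers))
    if (length(kmers) == 0L) idx <- integer(0)
    enc <- build_indicator_vectors(kmers[idx], spec)
    batches[[i]] <- lapply(seq_len(spec$b), function(b) {
      he_encrypt(backend, enc$vectors[b, ])
    })
  }
  structure(list(batches = batches, spec = spec, n_kmers = length(kmers)),
            class = "encrypted_kmers")
}

#' Protocol steps of the homomorphic equality test
#'
#' Step 1 rotates the block-`b` indicator ciphertext by `N * K_ref[b]`, so
#' batch slot `n` becomes 1 exactly when user block `K^(n)[b]` equals the
#' panel block value. Step 2 multiplies the rotated blocks componentwise, so
#' slot `n` flags full K-mer equality. Step 3 sums over a panel group's
#' K-mers, counting (0/1 under the design guarantee of distinct panel
#' K-mers) matches per user K-mer. Step 4 rotates-and-adds so slot 0 carries
#' the total match count for the group.
#'
#' @param backend An `he_backend` (hospital side: public material only).
#' @param c_b Indicator ciphertext for one block.
#' @param ref_value Quaternary value of the panel K-mer's block `b`.
#' @param n_batch Batch size N.
#' @param rotated List of the B rotated block ciphertexts of one panel K-mer.
#' @param d_list List of per-panel-K-mer equality ciphertexts in one group.
#' @param d Group equality-count ciphertext.
#' @name protocol-steps
NULL

#' @rdname protocol-steps
#' @export
step1_rotate <- function(backend, c_b, ref_value, n_batch) {
  he_rotate(backend, c_b, n_batch * ref_value)
}

#' @rdname protocol-steps
#' @export
step2_block_product <- function(backend, rotated) {
  he_relin(backend, Reduce(function(x, y) he_mult_lazy(backend, x, y), rotated))
}

#' @rdname protocol-steps
#' @export
step3_sum <- function(backend, d_list) {
  if (length(d_list) == 0L) return(he_zero(backend))
  Reduce(function(x, y) he_add(backend, x, y), d_list)
}

#' @rdname protocol-steps
#' @export
step4_aggregate <- function(backend, d, n_batch) {
  out <- d
  for (r in seq_len(n_batch - 1L)) {
    out <- he_add(backend, out, he_rotate(backend, d, r))
  }
  out
}

# Balanced (tree) lazy product keeping the extended ciphertext small.
lazy_tree_product <- function(backend, cts) {
  while (length(cts) > 1L) {
    nxt <- vector("list", ceiling(length(cts) / 2))
    for (i in seq_along(nxt)) {
      a <- cts[[2 * i - 1]]
      nxt[[i]] <- if (2 * i <= length(cts)) he_mult_lazy(backend, a, cts[[2 * i]]) else a
    }
    cts <- nxt
  }
  cts[[1]]
}

#' Run the homomorphic equality test against a panel
#'
#' Executes protocol Steps 1–4 once per (residue, allele) group: the batched
#' user indicator ciphertexts are rotated by each panel K-mer's block codes,
#' multiplied across blocks, summed over the group's K-mers and across
#' batches, and finally rotate-aggregated so slot 0 of each result encrypts
#' the number of user K-mers equal to a K-mer of that group. The hospital
#' needs only public key material and the plaintext panel codes.
#'
#' @param enc_user `encrypted_kmers` from [encrypt_user_kmers()].
#' @param plan A [protocol_plan()].
#' @param backend An `he_backend` holding evaluation/rotation key material.
#' @return Object of class `match_result`: one count ciphertext per group.
#' @export
match_panel <- function(enc_user, plan, backend) {
  spec <- plan$spec
  if (!identical(spec$slots, enc_user$spec$slots) || !identical(spec$b, enc_user$spec$b)) {
    abort("encrypted batches were built for a different block layout than this plan")
  }
  if (spec$n_batch >= he_ptmod(backend)) {
    abort(sprintf("batch size N = %d reaches the plaintext modulus %d: counts would wrap",
                  spec$n_batch, he_ptmod(backend)))
  }
  if (enc_user$n_kmers >= he_ptmod(backend)) {
    warn(sprintf(
      "user k-mer count %d reaches the plaintext modulus %d: a count could wrap if nearly all k-mers hit one group",
      enc_user$n_kmers, he_ptmod(backend)))
  }
  ng <- nrow(plan$groups)
  dsum <- rep(list(NULL), ng)
  for (batch in enc_user$batches) {
    rot_cache <- new.env(parent = emptyenv())
    rotated <- function(b, value) {
      key <- paste0(b, ":", value)
      got <- rot_cache[[key]]
      if (is.null(got)) {
        got <- step1_rotate(backend, batch[[b]], value, spec$n_batch)
        rot_cache[[key]] <- got
      }
      got
    }
    for (g in seq_len(ng)) {
      codes <- plan$groups$codes[[g]]
      d_ext <- NULL
      for (m in seq_len(ncol(codes))) {
        cts <- lapply(seq_len(spec$b), function(b) rotated(b, codes[b, m]))
        dm <- lazy_tree_product(backend, cts)
        d_ext <- if (is.null(d_ext)) dm else he_add(backend, d_ext, dm)
      }
      d_ext <- he_relin(backend, d_ext)
      dsum[[g]] <- if (is.null(dsum[[g]])) d_ext else he_add(backend, dsum[[g]], d_ext)
    }
  }
  counts <- lapply(dsum, function(d) step4_aggregate(backend, d, spec$n_batch))
  structure(list(groups = plan$groups[, c("residue_id", "allele")],
                 counts = counts, n_user_kmers = enc_user$n_kmers, spec = spec),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> encrypted counts for %d (residue, allele) groups over %d user k-mers\n",
              nrow(x$groups), x$n_user_kmers))
  invisible(x)
}

#' Decrypt the per-SNP match counts and call genotypes
#'
#' Patient-side decryption of a [match_panel()] result. Slot 0 of each group
#' ciphertext is the match count; a residue with both counts zero is flagged
#' as no-coverage, signalling a possible false negative rather than a
#' confident reference call.
#'
#' @param backend The patient-side backend (holds the secret key).
#' @param result A `match_result`.
#' @return `snp_call_report`: tibble with `residue_id`, `ref_count`,
#'   `alt_count`, and `call` in `ref`, `alt`, `het`, `no_coverage`.
#' @export
decrypt_report <- function(backend, result) {
  cnt <- vapply(result$counts, function(ct) as.numeric(he_decrypt(backend, ct)[1]), numeric(1))
  long <- dplyr::mutate(result$groups, count = cnt)
  wide <- tidyr::pivot_wider(long, names_from = "allele", values_from = "count",
                             values_fill = 0)
  if (is.null(wide$ref)) wide$ref <- 0
  if (is.null(wide$alt)) wide$alt <- 0
  out <- tibble(
    residue_id = wide$residue_id,
    ref_count = wide$ref,
    alt_count = wide$alt
  )
  out$call <- dplyr::case_when(
    out$ref_count > 0 & out$alt_count > 0 ~ "het",
    out$ref_count > 0 ~ "ref",
    out$alt_count > 0 ~ "alt",
    TRUE ~ "no_coverage"
  )
  class(out) <- c("snp_call_report", class(out))
  out
}

#' @export
tidy.snp_call_report <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.snp_call_report <- function(x, ...) {
  tibble(n_residues = nrow(x),
         n_called = sum(x$call != "no_coverage"),
         n_het = sum(x$call == "het"),
         n_no_coverage = sum(x$call == "no_coverage"))
}

#' @rdname decrypt_report
#' @param object An `snp_call_report`.
#' @param ... Ignored.
#' @export
autoplot.snp_call_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(unclass(object)),
                              c("ref_count", "alt_count"),
                              names_to = "allele", values_to = "count")
  long$allele <- sub("_count", "", long$allele)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue_id, y = .data$count,
                                     fill = .data$allele)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "panel residue", y = "matching k-mer count",
                  title = "Decrypted per-SNP match counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
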