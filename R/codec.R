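#' Encode a K-mer as a quaternary integer
#'
#' Maps A,C,G,T to 0,1,2,3 and reads the K-mer as a base-4 number with the
#' first base most significant, e.g. `"GACT"` is 2*4^3 + 0*4^2 + 1*4 + 3 = 135.
#'
#' @param kmer Character vector of K-mers over `{A,C,G,T}`.
#' @return Numeric vector of base-4 values (exact for K <= 26).
#' @examples
#' to_quaternary_int("GACT")
#' @export
to_quaternary_int <- function(kmer) {
  assert_dna(kmer, "k-mer")
  if (any(nchar(kmer) > 26L)) abort("k-mer too long to encode exactly as a double (max 26 bases)")
  vapply(kmer, function(s) {
    d <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES) - 1
    sum(d * 4^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Split a K-mer into fixed-size blocks
#'
#' Blocks of `l` bases, the final short block right-padded with `A` (value 0)
#' so all blocks encode to the same range; panel K-mers are padded the same
#' way, so matching semantics are unchanged.
#'
#' @param kmer Single K-mer string.
#' @param l Block size in bases (>= 1).
#' @return Character vector of `ceiling(K/l)` block strings.
#' @examples
#' split_blocks("CATCAT", 2)
#' @export
split_blocks <- function(kmer, l) {
  l <- as.integer(l)
  if (l < 1L) abort("block size l must be >= 1")
  k <- nchar(kmer)
  b <- ceiling(k / l)
  padded <- paste0(kmer, strrep("A", b * l - k))
  starts <- (seq_len(b) - 1L) * l + 1L
  substring(padded, starts, starts + l - 1L)
}

#' Choose the slot-vector dimension for a block size and batch size
#'
#' The indicator index `K[b]*N + n` ranges up to `4^l * N - 1`, so the slot
#' count is the smallest power of two that is at least `4^l * N`.
#'
#' @param l Block size in bases.
#' @param n_batch Number of user K-mers per batch (N).
#' @param capacity Optional backend slot capacity; exceeding it is an error
#'   instructing a smaller batch.
#' @return Integer power of two.
#' @examples
#' choose_slots(2, 2)
#' @export
choose_slots <- function(l, n_batch, capacity = NULL) {
  if (l < 1 || n_batch < 1) abort("l and n_batch must be >= 1")
  s <- next_power_of_two(4^l * n_batch)
  if (!is.null(capacity) && s > capacity) {
    abort(sprintf(
      "slot demand %d exceeds backend capacity %d; split the user K-mers into smaller batches (reduce N or L)",
      s, capacity))
  }
  s
}

#' Block/batch layout for indicator-vector encoding
#'
#' @param k K-mer length.
#' @param l Block size in bases.
#' @param n_batch User K-mers per batch (N).
#' @param capacity Optional backend slot capacity.
#' @return A `block_spec` with fields `k`, `l`, `b` (number of blocks),
#'   `n_batch`, `slots`.
#' @export
block_spec <- function(k, l, n_batch, capacity = NULL) {
  structure(list(k = as.integer(k), l = as.integer(l),
                 b = as.integer(ceiling(k / l)),
                 n_batch = as.integer(n_batch),
                 slots = as.integer(choose_slots(l, n_batch, capacity))),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<block_spec> K = %d split into B = %d blocks of L = %d; N = %d k-mers/batch, %d slots\n",
              x$k, x$b, x$l, x$n_batch, x$slots))
  invisible(x)
}

# B x n_kmers matrix of block values for a set of K-mers.
block_values <- function(kmers, spec) {
  vapply(kmers, function(km) to_quaternary_int(split_blocks(km, spec$l)),
         numeric(spec$b))
}

#' Build slot-indexed indicator vectors for one batch of user K-mers
#'
#' For block `b`, slot `i` of vector `v_b` is 1 exactly when
#' `i = K^(n)[b] * N + n` for some user K-mer `n` in the batch; the map is
#' injective because `n < N`. Unused batch positions stay all-zero.
#'
#' @param user_kmers Character vector of at most `spec$n_batch` K-mers of
#'   length `spec$k`.
#' @param spec A [block_spec()].
#' @return Object of class `encoded_vectors`: integer matrix `vectors`
#'   (`b` rows by `slots` columns) plus the k-mer order.
#' @export
build_indicator_vectors <- function(user_kmers, spec) {
  if (length(user_kmers) > spec$n_batch) {
    abort(sprintf("batch holds at most N = %d k-mers", spec$n_batch))
  }
  if (length(user_kmers) > 0 && any(nchar(user_kmers) != spec$k)) {
    abort(sprintf("all user k-mers must have length K = %d", spec$k))
  }
  vec <- matrix(0L, nrow = spec$b, ncol = spec$slots)
  if (length(user_kmers) > 0) {
    bv <- block_values(user_kmers, spec)   # b x n
    if (spec$b == 1L) bv <- matrix(bv, nrow = 1L)
    for (b in seq_len(spec$b)) {
      idx <- bv[b, ] * spec$n_batch + (seq_along(user_kmers) - 1L)
      vec[b, idx + 1L] <- 1L
    }
  }
  structure(list(vectors = vec, spec = spec, kmer_order = user_kmers),
            class = "encoded_vectors")
}

#' Recover block values from indicator vectors
#'
#' Inverse of [build_indicator_vectors()]: positions of the set bits give
#' every `K^(n)[b]`.
#'
#' @param enc An `encoded_vectors` object.
#' @return `b` x `n` matrix of block values.
#' @export
decode_indicator_vectors <- function(enc) {
  spec <- enc$spec
  n <- length(enc$kmer_order)
  out <- matrix(NA_real_, nrow = spec$b, ncol = n)
  for (b in seq_len(spec$b)) {
    idx <- which(enc$vectors[b, ] == 1L) - 1L
    nn <- idx %% spec$n_batch
    out[b, nn + 1L] <- (idx - nn) / spec$n_batch
  }
  out
}

#' Chunk sequencing reads into user K-mers
#'
#' All stride-1 windows of length `k` from each read and, by default, from
#' its reverse complement (paired reads originate from both strands while
#' panel K-mers are forward-strand only). Windows containing `N` are dropped;
#' duplicates are retained.
#'
#' @param reads Character vector of read sequences (or a tibble with a
#'   `seq` column, as produced by [simulate_reads()]).
#' @param k Window length.
#' @param include_reverse_complement Also window the reverse complement
#'   (default TRUE).
#' @return Tibble with columns `read`, `orientation`, `pos` (0-based window
#'   start within the oriented read) and `kmer`.
#' @export
kmerize_reads <- function(reads, k, include_reverse_complement = TRUE) {
  if (is.data.frame(reads)) reads <- reads$seq
  assert_dna(reads, "read", allow_n = TRUE)
  orient <- function(seqs, label) {
    rows <- purrr::imap(seqs, function(s, i) {
      w <- str_windows(s, k)
      if (length(w) == 0) return(NULL)
      tibble(read = i, orientation = label, pos = seq_along(w) - 1L, kmer = w)
    })
    dplyr::bind_rows(rows)
  }
  out <- orient(reads, "fwd")
  if (include_reverse_complement) {
    out <- dplyr::bind_rows(out, orient(reverse_complement(reads), "rev"))
  }
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(read = integer(0), orientation = character(0),
                  pos = integer(0), kmer = character(0)))
  }
  out[!grepl("N", out$kmer, fixed = TRUE), , drop = FALSE]
}
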