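#' Hamming distance between two equal-length sequences
#'
#' The PDT criteria generalise the K-mer equality test to a Hamming-distance
#' lower bound, so distances between panel K-mers decide whether a K is safe.
#'
#' @param a,b Equal-length character scalars.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming(): sequences must have equal length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Sequence of an entity with one residue switched to a given allele and all
# other residues held at ref (the entity sequence itself is all-ref).
allele_version <- function(sequence, offset, allele) {
  paste0(substr(sequence, 1L, offset), allele, substring(sequence, offset + 2L))
}

#' K-merize a preprocessed panel into SNP and background sets
#'
#' Slides a window of length `k` (stride 1) over every allele version of each
#' entity sequence. Windows covering a residue position form set A, labelled
#' by (residue, allele); all remaining windows form the background set B,
#' deduplicated by sequence. Set A keeps both allele versions so the protocol
#' can report ref/alt status.
#'
#' @param panel An `snp_panel`.
#' @param k Window length (>= 1, at most the shortest entity).
#' @return An object of class `kmer_sets` with tibbles `set_a` (columns
#'   `seq`, `entity_id`, `residue_id`, `allele`, `offset`) and `set_b`
#'   (columns `seq`, `entity_id`, `offset`).
#' @export
kmerize_panel <- function(panel, k) {
  k <- as.integer(k)
  if (k < 1L) abort("k must be >= 1")
  lens <- nchar(panel$entities$sequence)
  if (any(lens < k)) {
    abort(sprintf("k = %d exceeds entity %s (length %d)",
                  k, panel$entities$entity_id[which.min(lens)], min(lens)))
  }
  a_rows <- list(); b_rows <- list()
  for (ei in seq_len(nrow(panel$entities))) {
    ent <- panel$entities[ei, ]
    resid <- panel$residues[panel$residues$entity_id == ent$entity_id, , drop = FALSE]
    len <- nchar(ent$sequence)
    covered <- function(starts, off) starts <= off & starts + k - 1L >= off

    for (ri in seq_len(nrow(resid))) {
      off <- resid$offset[ri]
      if (off < k - 1L || off > len - k) {
        abort(sprintf("residue %s sits %d bp from an end of %s; need >= K (%d) on both sides",
                      resid$residue_id[ri], min(off, len - 1L - off), ent$entity_id, k))
      }
      for (al in c("ref", "alt")) {
        base <- if (al == "ref") resid$ref[ri] else resid$alt[ri]
        vseq <- allele_version(ent$sequence, off, base)
        starts <- (off - k + 1L):off
        a_rows[[length(a_rows) + 1L]] <- tibble(
          seq = substring(vseq, starts + 1L, starts + k),
          entity_id = ent$entity_id, residue_id = resid$residue_id[ri],
          allele = al, offset = starts
        )
        # background windows of this allele version (not covering any residue)
        allst <- 0:(len - k)
        bg <- allst[!Reduce(`|`, lapply(resid$offset, function(o) covered(allst, o)))]
        b_rows[[length(b_rows) + 1L]] <- tibble(
          seq = substring(vseq, bg + 1L, bg + k),
          entity_id = ent$entity_id, offset = bg
        )
      }
    }
    if (nrow(resid) == 0L) {
      allst <- 0:(len - k)
      b_rows[[length(b_rows) + 1L]] <- tibble(
        seq = substring(ent$sequence, allst + 1L, allst + k),
        entity_id = ent$entity_id, offset = allst
      )
    }
  }
  set_a <- if (length(a_rows)) dplyr::bind_rows(a_rows) else
    tibble(seq = character(0), entity_id = character(0), residue_id = character(0),
           allele = character(0), offset = integer(0))
  set_b <- if (length(b_rows)) dplyr::distinct(dplyr::bind_rows(b_rows), .data$seq, .keep_all = TRUE) else
    tibble(seq = character(0), entity_id = character(0), offset = integer(0))
  structure(list(k = k, set_a = set_a, set_b = set_b), class = "kmer_sets")
}

#' @export
print.kmer_sets <- function(x, ...) {
  cat(sprintf("<kmer_sets> K = %d: |A| = %d (SNP-covering), |B| = %d (background)\n",
              x$k, nrow(x$set_a), nrow(x$set_b)))
  invisible(x)
}

locus_key <- function(entity_id, offset) {
  # same-locus pairs (same entity and window start) are exempt from the PDT
  # conditions: distinguishing a ref from an alt window at one locus is the
  # assay's purpose, and such pairs are at distance 1 by construction.
  as.integer(factor(paste(entity_id, offset)))
}

#' Check the PDT distinctness conditions for a K-mer length
#'
#' Passes when (i) every cross-locus pair within set A and (ii) every A-by-B
#' pair is at Hamming distance greater than `pdt`. Pairs sharing an entity
#' and window start (the two allele versions of one locus) are exempt.
#'
#' @param kmer_sets A `kmer_sets` object from [kmerize_panel()].
#' @param pdt Point Deviation Tolerance (>= 0).
#' @param max_violations Stop after recording this many offending pairs.
#' @return List with `ok` (logical) and `violations`, a tibble of offending
#'   pairs (`seq1`, `seq2`, `dist`, `pair_type`).
#' @export
check_pdt_conditions <- function(kmer_sets, pdt, max_violations = 20L) {
  if (pdt < 0) abort("pdt must be >= 0")
  a <- kmer_sets$set_a; b <- kmer_sets$set_b
  keys_ab <- locus_key(c(a$entity_id, b$entity_id), c(a$offset, b$offset))
  key_a <- keys_ab[seq_len(nrow(a))]
  key_b <- keys_ab[nrow(a) + seq_len(nrow(b))]
  viol <- list()
  r1 <- .eng_close_pairs(a$seq, character(0), key_a, integer(0),
                         as.integer(pdt), TRUE, as.integer(max_violations))
  if (!r1$ok) {
    viol[[1]] <- tibble(seq1 = a$seq[r1$i], seq2 = a$seq[r1$j],
                        dist = r1$dist, pair_type = "A-A")
  }
  left <- max_violations - sum(vapply(viol, nrow, 1L))
  if (left > 0 && nrow(b) > 0 && nrow(a) > 0) {
    r2 <- .eng_close_pairs(a$seq, b$seq, key_a, key_b,
                           as.integer(pdt), FALSE, as.integer(left))
    if (!r2$ok) {
      viol[[2]] <- tibble(seq1 = a$seq[r2$i], seq2 = b$seq[r2$j],
                          dist = r2$dist, pair_type = "A-B")
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(seq1 = character(0), seq2 = character(0), dist = integer(0), pair_type = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Find the minimum K-mer length satisfying the PDT conditions
#'
#' Searches K upward from `k_floor` (distances are bounded by K, so no
#' K <= PDT can pass) and returns the smallest K for which
#' [check_pdt_conditions()] holds, together with the offending pairs at K-1.
#'
#' @param panel An `snp_panel`.
#' @param pdt Point Deviation Tolerance.
#' @param k_floor Smallest K to try; default `pdt + 1`.
#' @param k_cap Largest K to try before giving up.
#' @return Object of class `kmer_design` with elements `k`, `pdt`,
#'   `violations_at_k_minus_1`, and the `kmer_sets` at the chosen K.
#' @export
find_min_k <- function(panel, pdt, k_floor = pdt + 1, k_cap = 40L) {
  if (k_cap < k_floor) abort("k_cap must be >= k_floor")
  prev_viol <- NULL
  for (k in seq.int(k_floor, k_cap)) {
    ks <- kmerize_panel(panel, k)
    chk <- check_pdt_conditions(ks, pdt, max_violations = 1L)
    if (chk$ok) {
      viol_prev <- if (k > k_floor) {
        check_pdt_conditions(kmerize_panel(panel, k - 1L), pdt)$violations
      } else {
        tibble(seq1 = character(0), seq2 = character(0), dist = integer(0), pair_type = character(0))
      }
      return(structure(
        list(k = k, pdt = pdt, n_residues = panel$n_residues,
             violations_at_k_minus_1 = viol_prev, kmer_sets = ks),
        class = "kmer_design"
      ))
    }
    prev_viol <- chk$violations
  }
  abort(sprintf(
    "no K <= %d satisfies the PDT-%d conditions; blocking pair: %s / %s (distance %d) — the panel needs redesign",
    k_cap, pdt, prev_viol$seq1[1], prev_viol$seq2[1], prev_viol$dist[1]
  ))
}

#' @export
print.kmer_design <- function(x, ...) {
  cat(sprintf("<kmer_design> minimal K = %d at PDT = %d (%d residues; |A| = %d, |B| = %d)\n",
              x$k, x$pdt, x$n_residues, nrow(x$kmer_sets$set_a), nrow(x$kmer_sets$set_b)))
  invisible(x)
}

#' @export
tidy.kmer_design <- function(x, ...) x$violations_at_k_minus_1

#' @export
glance.kmer_design <- function(x, ...) {
  tibble(k = x$k, pdt = x$pdt, n_residues = x$n_residues,
         n_set_a = nrow(x$kmer_sets$set_a), n_set_b = nrow(x$kmer_sets$set_b),
         n_violations_at_k_minus_1 = nrow(x$violations_at_k_minus_1))
}

#' Design report as JSON
#'
#' @param design A `kmer_design`.
#' @param panel The `snp_panel` it was computed from.
#' @param path Output path.
#' @export
write_design_report <- function(design, panel, path) {
  rep <- list(K = design$k, PDT = design$pdt, N = panel$n_residues,
              discarded = panel$discarded,
              violations_at_K_minus_1 = design$violations_at_k_minus_1)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
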