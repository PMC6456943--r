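# Independent reference implementations used to cross-check the package.
# Everything here is deliberately naive (quadratic loops, direct string
# scans) and shares no code with the implementation under test.

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# Assemble an snp_panel directly from explicit entity sequences, bypassing
# preprocess_panel, for precise control in unit tests.
make_panel <- function(sequences, residues) {
  ents <- tibble::tibble(
    entity_id = names(sequences), chrom = "t", start = 0L,
    sequence = unname(sequences)
  )
  structure(list(entities = ents, residues = residues,
                 discarded = tibble::tibble(residue_id = character(0), reason = character(0)),
                 n_residues = nrow(residues), n_input = nrow(residues)),
            class = "snp_panel")
}

# Naive window enumeration of sets A and B for one panel, PDT conditions by
# all-pairs comparison, and exhaustive ascending-K search.
oracle_kmer_sets <- function(panel, k) {
  A <- list(); B <- character(0)
  for (ei in seq_len(nrow(panel$entities))) {
    ent <- panel$entities[ei, ]
    resid <- panel$residues[panel$residues$entity_id == ent$entity_id, ]
    len <- nchar(ent$sequence)
    for (ri in seq_len(nrow(resid))) {
      for (al in c("ref", "alt")) {
        base <- if (al == "ref") resid$ref[ri] else resid$alt[ri]
        v <- ent$sequence
        substr(v, resid$offset[ri] + 1, resid$offset[ri] + 1) <- base
        for (s in 0:(len - k)) {
          w <- substr(v, s + 1, s + k)
          covers <- any(resid$offset >= s & resid$offset <= s + k - 1)
          if (resid$offset[ri] >= s && resid$offset[ri] <= s + k - 1) {
            A[[length(A) + 1]] <- list(seq = w, key = paste(ent$entity_id, s))
          } else if (!covers) {
            B <- c(B, w)
          }
        }
      }
    }
  }
  list(A = A, B = unique(B))
}

oracle_pdt_ok <- function(panel, k, pdt) {
  ks <- oracle_kmer_sets(panel, k)
  A <- ks$A
  if (length(A) >= 2) {
    for (i in seq_len(length(A) - 1)) for (j in (i + 1):length(A)) {
      if (A[[i]]$key == A[[j]]$key) next
      if (oracle_hamming(A[[i]]$seq, A[[j]]$seq) <= pdt) return(FALSE)
    }
  }
  for (i in seq_along(A)) for (bseq in ks$B) {
    if (oracle_hamming(A[[i]]$seq, bseq) <= pdt) return(FALSE)
  }
  TRUE
}

oracle_min_k <- function(panel, pdt, k_cap = 30) {
  for (k in (pdt + 1):k_cap) {
    if (oracle_pdt_ok(panel, k, pdt)) return(k)
  }
  NA_integer_
}

# Count, for each (residue, allele) group of a protocol plan, the user
# K-mers exactly equal to one of the group's K-mer strings.
oracle_match_counts <- function(user_kmers, plan) {
  vapply(seq_len(nrow(plan$groups)),
         function(g) sum(user_kmers %in% plan$groups$kmers[[g]]),
         numeric(1))
}

random_panel_residues <- function(n, flank, seed, chrom = "t") {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      fl <- paste(sample(c("A", "C", "G", "T"), 2 * flank + 1, TRUE), collapse = "")
      ref <- substr(fl, flank + 1, flank + 1)
      tibble::tibble(
        id = sprintf("r%02d", i), chrom = chrom,
        pos = 100000L * i, ref = ref,
        alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
        flank5 = substr(fl, 1, flank), flank3 = substring(fl, flank + 2)
      )
    })
  })
}
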