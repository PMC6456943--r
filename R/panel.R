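#' Build a table of SNP panel residues
#'
#' A panel residue is one disease-associated SNP with its reference and
#' alternate alleles and the flanking sequence the assay will observe around
#' it. Positions are 0-based genomic coordinates.
#'
#' @param df Data frame with columns `id`, `chrom`, `pos` (0-based integer),
#'   `ref`, `alt`, and (after flanks are attached) `flank5`, `flank3`.
#' @return A validated tibble of residues.
#' @export
snp_residues <- function(df) {
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("missing residue columns: ", paste(miss, collapse = ", ")))
  df <- as_tibble(df)
  df$pos <- as.integer(df$pos)
  if (anyDuplicated(df$id)) abort("residue ids must be unique")
  if (any(df$ref == df$alt)) abort("ref and alt alleles must differ")
  assert_dna(df$ref, "ref allele"); assert_dna(df$alt, "alt allele")
  if (any(nchar(df$ref) != 1L) || any(nchar(df$alt) != 1L)) {
    abort("alleles must be single nucleotides")
  }
  if (!is.null(df[["flank5"]])) assert_dna(df[["flank5"]], "flank5")
  if (!is.null(df[["flank3"]])) assert_dna(df[["flank3"]], "flank3")
  df
}

#' Read a panel definition TSV
#'
#' Expects columns `id`, `chrom`, `pos` (0-based), `ref`, `alt`.
#'
#' @param path Path to a tab-separated panel file.
#' @return Tibble of residues (without flanks).
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  snp_residues(df)
}

#' @rdname read_panel_tsv
#' @param residues Residue tibble to write.
#' @export
write_panel_tsv <- function(residues, path) {
  utils::write.table(residues[, c("id", "chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach flanking sequences to panel residues
#'
#' Flanks come as a FASTA keyed by residue id, each record holding the full
#' flanked sequence `flank5 + ref + flank3` (symmetric flanks), or as an
#' already-named character vector of such sequences.
#'
#' @param residues Residue tibble from [snp_residues()] or [read_panel_tsv()].
#' @param flanks Named character vector, or path to a FASTA file.
#' @return Residue tibble with `flank5`/`flank3` columns filled in.
#' @export
attach_flanks <- function(residues, flanks) {
  if (is.character(flanks) && length(flanks) == 1 && file.exists(flanks)) {
    ss <- Biostrings::readDNAStringSet(flanks)
    flanks <- setNames(as.character(ss), names(ss))
  }
  miss <- setdiff(residues$id, names(flanks))
  if (length(miss) > 0) abort(paste0("no flank sequence for residues: ", paste(head(miss, 5), collapse = ", ")))
  seqs <- unname(flanks[residues$id])
  len <- nchar(seqs)
  if (any(len %% 2L != 1L)) abort("flanked sequences must have odd length (symmetric flanks around the SNP)")
  half <- (len - 1L) %/% 2L
  centre <- substr(seqs, half + 1L, half + 1L)
  if (any(centre != residues$ref)) {
    abort("centre base of a flanked sequence does not match the ref allele")
  }
  residues$flank5 <- substr(seqs, 1L, half)
  residues$flank3 <- substring(seqs, half + 2L)
  snp_residues(residues)
}

#' @rdname attach_flanks
#' @param path Output FASTA path.
#' @export
write_flanks_fasta <- function(residues, path) {
  seqs <- paste0(residues$flank5, residues$ref, residues$flank3)
  ss <- Biostrings::DNAStringSet(setNames(seqs, residues$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

residue_sequence <- function(residues) {
  paste0(residues$flank5, residues$ref, residues$flank3)
}

#' Preprocess a panel: merge or discard residues with overlapping flanks
#'
#' Residues whose flanked regions share sequence are handled before K-mer
#' design. When the shared stretch is identical and of credible length
#' (between `full_overlap_cutoff` and `max_overlap` base pairs) the two
#' residues are merged into one entity with an extended sequence. A shared
#' stretch that disagrees at any position, or that is longer than
#' `max_overlap` (longer than a short read, so the loci cannot be told apart),
#' causes one residue of the pair — chosen by a seeded coin flip — to be
#' discarded. Identical overlaps shorter than `full_overlap_cutoff` are
#' treated as chance similarity and left alone.
#'
#' @param residues Residue tibble with flanks attached.
#' @param full_overlap_cutoff Minimum identical overlap (bp) accepted for a
#'   merge; default 100.
#' @param max_overlap Maximum overlap (bp) a merge may span; default 150.
#' @param seed Integer seed for the discard coin flips.
#' @return An object of class `snp_panel`: entity table, residue map,
#'   discard log, and the surviving residue count `n_residues`.
#' @export
preprocess_panel <- function(residues, full_overlap_cutoff = 100, max_overlap = 150,
                             seed = NULL) {
  if (is.null(residues[["flank5"]]) || is.null(residues[["flank3"]])) {
    abort("residues need flank5/flank3 attached (see attach_flanks())")
  }
  res <- residues[order(residues$chrom, residues$pos), , drop = FALSE]
  res$.seq <- residue_sequence(res)
  res$.start <- res$pos - nchar(res$flank5)
  res$.len <- nchar(res$.seq)

  entities <- list()   # each: list(chrom, start, seq, residues = tibble rows)
  discarded <- list()
  flips <- with_seed(seed, runif(nrow(res)))

  drop_residue <- function(id, reason) {
    discarded[[length(discarded) + 1L]] <<- tibble(residue_id = id, reason = reason)
  }
  new_entity <- function(row) {
    entities[[length(entities) + 1L]] <<- list(
      chrom = row$chrom, start = row$.start, seq = row$.seq,
      residues = row[, c("id", "chrom", "pos", "ref", "alt")]
    )
  }

  for (i in seq_len(nrow(res))) {
    row <- res[i, ]
    le <- if (length(entities) > 0) entities[[length(entities)]] else NULL
    ov <- 0L
    if (!is.null(le) && identical(le$chrom, row$chrom)) {
      ent_end <- le$start + nchar(le$seq) - 1L
      ov <- min(ent_end - row$.start + 1L, row$.len, nchar(le$seq))
    }
    if (ov <= 0L) { new_entity(row); next }

    tail_seq <- substr(le$seq, nchar(le$seq) - ov + 1L, nchar(le$seq))
    head_seq <- substr(row$.seq, 1L, ov)
    agree <- identical(tail_seq, head_seq)

    if (agree && ov >= full_overlap_cutoff && ov <= max_overlap) {
      le$seq <- paste0(le$seq, substring(row$.seq, ov + 1L))
      le$residues <- dplyr::bind_rows(le$residues, row[, c("id", "chrom", "pos", "ref", "alt")])
      entities[[length(entities)]] <- le
    } else if (agree && ov < full_overlap_cutoff) {
      new_entity(row)   # chance-level similarity: keep both, unmerged
    } else {
      reason <- if (agree) "overlap_too_long" else "overlap_mismatch"
      prev <- le$residues[nrow(le$residues), ]
      if (flips[i] < 0.5 && nrow(le$residues) == 1L) {
        drop_residue(prev$id, reason)
        entities[[length(entities)]] <- NULL
        new_entity(row)
      } else {
        drop_residue(row$id, reason)
      }
    }
  }

  ent_tbl <- purrr::map2_dfr(entities, seq_along(entities), function(e, k) {
    tibble(entity_id = sprintf("entity_%03d", k), chrom = e$chrom,
           start = e$start, sequence = e$seq)
  })
  res_map <- purrr::map2_dfr(entities, seq_along(entities), function(e, k) {
    tibble(entity_id = sprintf("entity_%03d", k),
           residue_id = e$residues$id,
           offset = e$residues$pos - e$start,
           ref = e$residues$ref, alt = e$residues$alt)
  })
  disc <- if (length(discarded) > 0) dplyr::bind_rows(discarded) else {
    tibble(residue_id = character(0), reason = character(0))
  }
  structure(
    list(entities = ent_tbl, residues = res_map, discarded = disc,
         n_residues = nrow(res_map), n_input = nrow(res)),
    class = "snp_panel"
  )
}

#' Wrap already-preprocessed entities as a panel
#'
#' Used when residues are known to be non-overlapping (one entity per
#' residue), e.g. directly from the simulator.
#'
#' @inheritParams preprocess_panel
#' @export
panel_from_residues <- function(residues) {
  preprocess_panel(residues, seed = 0L)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d residues in %d entities (%d discarded, survival %.2f)\n",
              x$n_residues, nrow(x$entities), nrow(x$discarded),
              if (x$n_input > 0) x$n_residues / x$n_input else NA_real_))
  invisible(x)
}

#' @export
tidy.snp_panel <- function(x, ...) {
  dplyr::left_join(x$residues, x$entities[, c("entity_id", "chrom", "start")],
                   by = "entity_id")
}

#' @export
glance.snp_panel <- function(x, ...) {
  tibble(n_input = x$n_input, n_residues = x$n_residues,
         n_entities = nrow(x$entities), n_discarded = nrow(x$discarded),
         survival_rate = if (x$n_input > 0) x$n_residues / x$n_input else NA_real_)
}
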