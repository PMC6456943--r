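#' Configuration for the targeted-sequencing simulator
#'
#' Defaults reproduce the study conditions the package is tested under:
#' residues with 650 bp flanks on each side, paired 151 bp reads at mean
#' depth 10 with zero sequencing error, and a 50% per-residue chance that
#' the planted allele is the substitution (alt) rather than the reference.
#'
#' @param n_residues Number of panel residues.
#' @param flank_len Flank length per side, bp.
#' @param read_len Read length, bp.
#' @param paired Paired-end reads (outer insert drawn uniformly between
#'   twice the read length and `insert_len`, capped at the entity length)
#'   or single-end forward reads.
#' @param depth Mean sequencing depth over each entity.
#' @param substitution_prob Per-residue probability that the planted allele
#'   is alt.
#' @param insert_len Upper bound on the outer insert length for paired
#'   reads.
#' @param seed Integer seed; all simulator output is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_residues = 10, flank_len = 650, read_len = 151,
                       paired = TRUE, depth = 10, substitution_prob = 0.5,
                       insert_len = 500, seed = 1) {
  stopifnot(n_residues >= 1, flank_len >= 1, read_len >= 1, depth >= 0,
            substitution_prob >= 0, substitution_prob <= 1)
  structure(list(n_residues = as.integer(n_residues),
                 flank_len = as.integer(flank_len),
                 read_len = as.integer(read_len), paired = isTRUE(paired),
                 depth = depth, substitution_prob = substitution_prob,
                 insert_len = as.integer(insert_len), seed = as.integer(seed)),
            class = "sim_config")
}

# A fragment of uniform random sequence holding residue i at local offset
# flank_len; consecutive residues are spaced far apart unless forced to
# overlap for merge/discard testing.
#' Simulate a SNP panel with flanking sequence and planted genotypes
#'
#' Residues get i.i.d. uniform flanks (standing in for sampled coding
#' sequence), a random ref allele taken from the flank region and a distinct
#' alt allele; each residue's planted allele is alt with probability
#' `substitution_prob`. Optional forced-overlap pairs exercise the
#' preprocessing merge/discard branches.
#'
#' @param config A [sim_config()].
#' @param forced_overlap Character vector drawn from `"merge"`,
#'   `"mismatch"`, `"long"`: each appends a residue pair whose flanks share
#'   an identical 120 bp stretch, a 120 bp stretch with one mismatch, or an
#'   identical 200 bp stretch, respectively.
#' @param overlap_merge,overlap_long Shared-stretch lengths used by the
#'   forced pairs.
#' @return List with `residues` (flanked residue tibble), `truth`
#'   (`residue_id`, `planted_allele`) and the config; class `sim_panel`.
#' @export
simulate_panel <- function(config, forced_overlap = character(0),
                           overlap_merge = 120, overlap_long = 200) {
  f <- config$flank_len
  width <- 2L * f + 1L
  with_seed(config$seed, {
    rows <- list(); truth <- list()
    pos <- 10000L
    add_residue <- function(id, chrom, pos, seq_full) {
      ref <- substr(seq_full, f + 1L, f + 1L)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      rows[[length(rows) + 1L]] <<- tibble(
        id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
        flank5 = substr(seq_full, 1L, f), flank3 = substring(seq_full, f + 2L))
      truth[[length(truth) + 1L]] <<- tibble(
        id = id,
        planted_allele = if (runif(1) < config$substitution_prob) "alt" else "ref")
    }
    for (i in seq_len(config$n_residues)) {
      add_residue(sprintf("res%03d", i), "simA", pos, random_dna(width))
      pos <- pos + width + 1000L
    }
    for (j in seq_along(forced_overlap)) {
      kind <- match.arg(forced_overlap[j], c("merge", "mismatch", "long"))
      ov <- if (kind == "long") overlap_long else overlap_merge
      ov <- min(ov, width - 2L)          # keep both SNPs inside their own copy
      delta <- width - ov
      region <- random_dna(width + delta)
      seq1 <- substr(region, 1L, width)
      seq2 <- substring(region, delta + 1L)
      if (kind == "mismatch") {
        at <- sample(seq_len(ov %/% 2), 1L)   # inside the shared stretch
        old <- substr(seq2, at, at)
        substr(seq2, at, at) <- sample(setdiff(DNA_BASES, old), 1L)
      }
      chrom <- sprintf("simOV%d", j)
      add_residue(sprintf("ovl%03da", j), chrom, 50000L, seq1)
      add_residue(sprintf("ovl%03db", j), chrom, 50000L + delta, seq2)
    }
    structure(list(residues = snp_residues(dplyr::bind_rows(rows)),
                   truth = dplyr::bind_rows(truth), config = config),
              class = "sim_panel")
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d residues, %d bp flanks, seed %d (%d planted alt)\n",
              nrow(x$residues), x$config$flank_len, x$config$seed,
              sum(x$truth$planted_allele == "alt")))
  invisible(x)
}

# Entity sequence with every planted alt allele applied.
haplotype_sequence <- function(panel, truth, entity_id) {
  ent <- panel$entities[panel$entities$entity_id == entity_id, ]
  resid <- panel$residues[panel$residues$entity_id == entity_id, ]
  s <- ent$sequence
  for (i in seq_len(nrow(resid))) {
    planted <- truth$planted_allele[truth$id == resid$residue_id[i]]
    base <- if (identical(planted, "alt")) resid$alt[i] else resid$ref[i]
    substr(s, resid$offset[i] + 1L, resid$offset[i] + 1L) <- base
  }
  s
}

#' Simulate error-free targeted short reads from a preprocessed panel
#'
#' Reads are drawn uniformly from each entity's planted haplotype at the
#' configured depth with no sequencing error (matching an error-free
#' read-simulator setup). Paired mode emits a forward mate and the reverse
#' complement of the far end of the insert; single-end mode emits forward
#' reads only.
#'
#' @param panel An `snp_panel` (typically
#'   `preprocess_panel(sim$residues, ...)`).
#' @param truth Truth table from [simulate_panel()] (`sim$truth`).
#' @param config The [sim_config()].
#' @return Tibble of reads: `read_id`, `mate`, `seq`, `entity_id`, `start`
#'   (0-based on the entity), `strand`.
#' @export
simulate_reads <- function(panel, truth, config) {
  rl <- config$read_len
  with_seed(config$seed + 7919L, {
    out <- list()
    for (ei in seq_len(nrow(panel$entities))) {
      ent <- panel$entities[ei, ]
      len <- nchar(ent$sequence)
      if (len < rl) abort(sprintf("entity %s (%d bp) is shorter than a read", ent$entity_id, len))
      hap <- haplotype_sequence(panel, truth, ent$entity_id)
      if (config$paired) {
        ins_hi <- min(config$insert_len, len)
        ins_lo <- min(2L * rl, ins_hi)
        n_frag <- round(config$depth * len / (2 * rl))
        if (n_frag > 0) for (i in seq_len(n_frag)) {
          ins <- if (ins_hi > ins_lo) sample(ins_lo:ins_hi, 1L) else ins_hi
          s <- sample.int(len - ins + 1L, 1L) - 1L
          fwd <- substr(hap, s + 1L, s + rl)
          rev_start <- s + ins - rl
          rev <- reverse_complement(substr(hap, rev_start + 1L, rev_start + rl))
          rid <- sprintf("%s_frag%05d", ent$entity_id, i)
          out[[length(out) + 1L]] <- tibble(
            read_id = paste0(rid, c("/1", "/2")), mate = c(1L, 2L),
            seq = c(fwd, rev), entity_id = ent$entity_id,
            start = c(s, rev_start), strand = c("+", "-"))
        }
      } else {
        n_reads <- round(config$depth * len / rl)
        if (n_reads > 0) for (i in seq_len(n_reads)) {
          s <- sample.int(len - rl + 1L, 1L) - 1L
          out[[length(out) + 1L]] <- tibble(
            read_id = sprintf("%s_read%05d", ent$entity_id, i), mate = 1L,
            seq = substr(hap, s + 1L, s + rl), entity_id = ent$entity_id,
            start = s, strand = "+")
        }
      }
    }
    if (length(out) == 0) {
      return(tibble(read_id = character(0), mate = integer(0), seq = character(0),
                    entity_id = character(0), start = integer(0), strand = character(0)))
    }
    dplyr::bind_rows(out)
  })
}

#' Inject controlled point deviations into simulated reads
#'
#' Substitutes `count_per_read` bases in each read at positions at least
#' `min_distance_from_snp` away from every residue position the read
#' covers (or at one exact distance, for false-negative geometry studies).
#' With `count_per_read <= PDT`, every K-mer of a read carries at most PDT
#' deviations.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param panel The `snp_panel` the reads came from.
#' @param count_per_read Deviations per read.
#' @param min_distance_from_snp Minimum |distance| to any residue, bp.
#' @param exact_distance If not NULL, place a single deviation exactly this
#'   many bases 3' of the entity's (first) residue when the read covers that
#'   position.
#' @param seed Seed for the deviation positions.
#' @return The read tibble with mutated `seq` and a `deviations` list-column
#'   of 0-based entity positions touched.
#' @export
inject_deviations <- function(reads, panel, count_per_read = 1,
                              min_distance_from_snp = 0, exact_distance = NULL,
                              seed = 1) {
  res_by_entity <- split(panel$residues$offset, panel$residues$entity_id)
  with_seed(seed, {
    devs <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      s <- reads$start[i]; rl <- nchar(reads$seq[i])
      offs <- res_by_entity[[reads$entity_id[i]]] %||% integer(0)
      cand_entity <- s:(s + rl - 1L)
      if (!is.null(exact_distance)) {
        target <- offs[1] + exact_distance
        picks <- intersect(target, cand_entity)
      } else {
        ok <- rep(TRUE, length(cand_entity))
        for (o in offs) ok <- ok & abs(cand_entity - o) >= min_distance_from_snp
        cand <- cand_entity[ok]
        picks <- if (length(cand) == 0) integer(0) else
          sort(sample(cand, min(count_per_read, length(cand))))
      }
      if (length(picks) > 0) {
        sq <- reads$seq[i]
        for (gp in picks) {
          # entity position -> index within the oriented read sequence
          idx <- if (reads$strand[i] == "+") gp - s + 1L else rl - (gp - s)
          old <- substr(sq, idx, idx)
          substr(sq, idx, idx) <- sample(setdiff(DNA_BASES, old), 1L)
        }
        reads$seq[i] <- sq
      }
      devs[[i]] <- picks
    }
    reads$deviations <- devs
    reads
  })
}

#' Write / read simulated reads as FASTQ
#'
#' Constant high base quality (no error model). Paired reads go to `_1`/`_2`
#' files when `path2` is given.
#'
#' @param reads Read tibble.
#' @param path Output FASTQ for (first-mate) reads.
#' @param path2 Optional FASTQ for second mates.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  emit <- function(df, p) {
    ss <- Biostrings::DNAStringSet(setNames(df$seq, df$read_id))
    qs <- Biostrings::BStringSet(setNames(strrep("I", nchar(df$seq)), df$read_id))
    Biostrings::writeXStringSet(ss, p, format = "fastq", qualities = qs)
  }
  if (is.null(path2)) emit(reads, path) else {
    emit(reads[reads$mate == 1L, ], path)
    emit(reads[reads$mate == 2L, ], path2)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @param paths FASTQ file(s) to read.
#' @export
read_fastq <- function(paths) {
  dplyr::bind_rows(lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p, format = "fastq")
    tibble(read_id = names(ss), seq = as.character(ss))
  }))
}
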