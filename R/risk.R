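#' Number of unordered pairs among n items
#'
#' @param n Non-negative count (may exceed integer range; exact as a double
#'   up to 2^53).
#' @return `n * (n - 1) / 2`.
#' @examples
#' pair_count(116607)
#' @export
pair_count <- function(n) {
  n <- as.numeric(n)
  if (any(n < 0)) abort("n must be non-negative")
  n * (n - 1) / 2
}

#' Read a mutation catalog TSV (chrom, pos)
#'
#' @param path Tab-separated file with columns `chrom` and `pos`.
#' @return Catalog tibble, sorted and deduplicated within chromosome.
#' @export
read_mutation_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df))) abort("catalog needs chrom and pos columns")
  df <- dplyr::distinct(as_tibble(df[, c("chrom", "pos")]))
  dplyr::arrange(df, .data$chrom, .data$pos)
}

#' Count same-chromosome mutation pairs within a window
#'
#' Pairs with `|pos_i - pos_j| <= window` (boundary inclusive). Uses a
#' linear sweep over the sorted positions per chromosome.
#'
#' @param catalog Tibble with `chrom`, `pos` (or a bare numeric vector of
#'   positions on one chromosome).
#' @param window Proximity threshold in bp (default 32, one K-mer span).
#' @return Number of close pairs.
#' @export
count_close_pairs <- function(catalog, window = 32) {
  if (!is.data.frame(catalog)) catalog <- tibble(chrom = "chr", pos = catalog)
  total <- 0
  for (ch in unique(catalog$chrom)) {
    x <- sort(unique(catalog$pos[catalog$chrom == ch]))
    if (length(x) < 2) next
    upper <- findInterval(x + window, x)
    total <- total + sum(upper - seq_along(x))
  }
  total
}

#' False-negative risk of a panel from mutation proximity
#'
#' The chance that a randomly drawn pair of catalogued mutations lands
#' within one K-mer window is `close_pairs / total_pairs`; a panel of `N`
#' residues draws `choose(N, 2)` pairs, so the probability that at least one
#' pair collides — sabotaging the exact-match calling of a residue — is
#' `P = 1 - (1 - close_pairs/total_pairs)^choose(N, 2)`.
#'
#' @param close_pairs Number of catalog pairs within the window.
#' @param total_pairs Total number of catalog pairs.
#' @param n Panel size N (vectorised).
#' @param window Window size in bp used for `close_pairs` (metadata).
#' @return A `risk_estimate`: tibble with `n`, `close_pairs`, `total_pairs`,
#'   `window`, `p` (probability) and `p_percent`.
#' @export
fn_risk <- function(close_pairs, total_pairs, n, window = 32) {
  if (total_pairs <= 0) abort("total_pairs must be positive")
  if (close_pairs < 0 || close_pairs > total_pairs) {
    abort("close_pairs must lie in [0, total_pairs]")
  }
  rate <- close_pairs / total_pairs
  p <- -expm1(pair_count(n) * log1p(-rate))
  out <- tibble(n = n, close_pairs = close_pairs, total_pairs = total_pairs,
                window = window, p = p, p_percent = 100 * p)
  class(out) <- c("risk_estimate", class(out))
  out
}

#' @export
tidy.risk_estimate <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.risk_estimate <- function(x, ...) {
  tibble(window = x$window[1], pair_rate = x$close_pairs[1] / x$total_pairs[1],
         n_min = min(x$n), n_max = max(x$n), p_max = max(x$p))
}

#' @rdname fn_risk
#' @param object A `risk_estimate`.
#' @param ... Ignored.
#' @export
autoplot.risk_estimate <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$n, y = .data$p_percent)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "panel size N", y = "false-negative risk P (%)",
                  title = sprintf("Risk of two residues within a %d bp window",
                                  object$window[1])) +
    ggplot2::theme_minimal()
}

#' Chance of an identical flank overlap of a given length
#'
#' Under a uniform base model the probability that two flanking sequences
#' share an identical overlap of `overlap_len` bp by chance is
#' `1 - (1 - 2 * 4^-overlap_len)^2` (either orientation of the pair).
#' Evaluated in log space so long overlaps underflow gracefully.
#'
#' @param overlap_len Overlap length in bp (>= 1).
#' @return Probability.
#' @examples
#' overlap_chance(1)
#' @export
overlap_chance <- function(overlap_len) {
  if (any(overlap_len < 1)) abort("overlap_len must be >= 1")
  x <- 2 * exp(-overlap_len * log(4))
  ifelse(x < 1e-15, 2 * x, -expm1(2 * log1p(-x)))
}
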