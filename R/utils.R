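DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s}",
                  what, if (allow_n) ",N" else ""))
  }
  invisible(x)
}

# All stride-1 windows of length k from one string; character(0) if too short.
str_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

is_power_of_two <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x - 1L)) == 0L

next_power_of_two <- function(x) {
  p <- 1
  while (p < x) p <- p * 2
  p
}
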